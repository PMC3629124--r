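# Term enrichment: exact hypergeometric (Fisher) tests of a query gene set
# against a background, GO-slim rollup of fine-grained annotations, and the
# comparison battery run across signatures, UNS and gene universe.
#
# The "genome" background throughout is the gene universe of the expression
# matrix (the array-universe convention), so the analysis is self-contained.

# restrict an annotation table to a gene universe (case-insensitive) and
# drop duplicate (gene, term) pairs
restrict_annotations <- function(annotations, universe) {
  keep <- annotations$gene %in_ci% universe
  a <- annotations[keep, c("gene", "term")]
  a[!duplicated(paste(toupper(a$gene), a$term)), ]
}

#' Exact hypergeometric term-enrichment test
#'
#' One-sided over-representation test: with N background genes of which K
#' carry the term, and a query of n genes of which k carry it, the p-value
#' is P(X >= k) for X ~ Hypergeometric(N, K, n) (exact tail sum).
#' Under-representation uses P(X <= k).
#'
#' @param query A [gene_set] or character vector; must be a subset of
#'   `background`.
#' @param background A [gene_set] or character vector (the universe).
#' @param annotations Data frame with columns `gene`, `term`.
#' @param term Term ID to test; must annotate at least one background gene.
#' @param alternative `"over"` (default) or `"under"`.
#' @return One-row data frame: `term`, `k`, `n`, `K`, `N`, `direction`
#'   (over/under by the enrichment ratio), `p`. The query members carrying
#'   the term are attached as attribute `members`.
#' @export
fisher_term_test <- function(query, background, annotations, term,
                             alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  q <- as_members(query)
  bg <- as_members(background)
  assert_that(all(q %in_ci% bg), "query must be a subset of the background")
  ann <- restrict_annotations(annotations, bg)
  with_term <- unique(ann$gene[ann$term == term])
  K <- length(with_term)
  assert_that(K >= 1L, sprintf("term '%s' annotates no background gene", term))
  N <- length(unique(toupper(bg)))
  n <- length(unique(toupper(q)))
  members <- q[q %in_ci% with_term]
  k <- length(members)
  p <- if (alternative == "over") {
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  structure(data.frame(term = term, k = k, n = n, K = K, N = N,
                       direction = if (k / n >= K / N) "over" else "under",
                       p = p, stringsAsFactors = FALSE),
            members = members)
}

#' Test every term of an annotation table
#'
#' Runs [fisher_term_test()] for each term annotating the background and
#' BH-adjusts the p-values within this comparison family.
#'
#' @inheritParams fisher_term_test
#' @return Data frame of `EnrichmentRecord` rows sorted by `p`, with `padj`
#'   added.
#' @export
enrich_terms <- function(query, background, annotations,
                         alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  bg <- as_members(background)
  ann <- restrict_annotations(annotations, bg)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    r <- fisher_term_test(query, bg, ann, tm, alternative)
    r$members <- paste(attr(r, "members"), collapse = ",")
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), direction = character(0),
                      p = numeric(0), padj = numeric(0), members = character(0)))
  }
  out$padj <- bh_adjust(out$p)
  out[order(out$p), ]
}

# transitive ancestor closure of one term in the (acyclic) ancestor map
ancestor_closure <- function(term, parents) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(parents$ancestor[parents$term %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Roll fine-grained annotations up to a GO-slim vocabulary
#'
#' True-path propagation: every (gene, term) pair is mapped to each slim
#' ancestor of the term (terms already in the slim map to themselves),
#' deduplicated. Terms with no slim ancestor are dropped from the result and
#' reported in the `unmapped` attribute.
#'
#' @param annotations Data frame with columns `gene`, `term`.
#' @param slim List with `terms` (data frame, column `term`) and `ancestors`
#'   (data frame, columns `term`, `ancestor`; acyclic).
#' @return Data frame `gene`, `term` on the slim vocabulary; attribute
#'   `unmapped` lists source terms that reached no slim term.
#' @export
slim_rollup <- function(annotations, slim) {
  assert_that(nrow(slim$terms) >= 1L, "slim vocabulary is empty")
  slim_ids <- slim$terms$term
  src_terms <- unique(annotations$term)
  term_to_slim <- lapply(src_terms, function(tm) {
    anc <- c(tm, ancestor_closure(tm, slim$ancestors))
    intersect(anc, slim_ids)
  })
  names(term_to_slim) <- src_terms
  unmapped <- src_terms[lengths(term_to_slim) == 0L]
  n_per <- lengths(term_to_slim)[annotations$term]
  out <- data.frame(
    gene = rep(annotations$gene, n_per),
    term = unlist(term_to_slim[annotations$term], use.names = FALSE),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(toupper(out$gene), out$term)), ]
  rownames(out) <- NULL
  structure(out, unmapped = unmapped)
}

#' Run the signature comparison battery
#'
#' Executes the full set of enrichment comparisons on the slim vocabulary:
#' UNS versus the gene universe (strict alpha), each signature versus the
#' universe (strict alpha), each signature versus the UNS, and each ordered
#' signature pair A versus B (query A, background A union B), both at the
#' comparison alpha. P-values are BH-adjusted within each comparison.
#' Also emits the per-signature x per-slim-term gene-content percentage
#' table used for side-by-side functional profiles.
#'
#' @param signatures Named list of [gene_set]s (TS, IVVPS, IVTPS); empty or
#'   missing signatures are skipped with a warning.
#' @param uns A `uns_result` or [gene_set] (the UNS).
#' @param genome A [gene_set] or character vector: the gene universe.
#' @param annotations Data frame `gene`, `term` (fine-grained).
#' @param slim Slim vocabulary as in [slim_rollup()].
#' @param config A [significance_config()].
#' @return List with `records` (one data frame of all comparisons, columns
#'   of [enrich_terms()] plus `comparison`, `alpha`, `significant`),
#'   `percent_table` (slim terms x signatures, percent of signature genes
#'   annotated to each term), and `flagged` (the significant subset of
#'   `records`).
#' @export
run_comparison_battery <- function(signatures, uns, genome, annotations, slim,
                                   config = significance_config()) {
  uns_set <- if (inherits(uns, "uns_result")) uns$uns else uns
  genome <- as_members(genome)
  slim_ann <- slim_rollup(annotations, slim)
  sigs <- Filter(function(s) length(s$members) > 0L, signatures)
  if (length(sigs) < length(signatures)) {
    warning("skipping empty signature(s): ",
            paste(setdiff(names(signatures), names(sigs)), collapse = ", "))
  }
  specs <- list(list(name = "UNS_vs_genome", q = uns_set, bg = genome,
                     alpha = config$enrich_alpha_strict))
  for (nm in names(sigs)) {
    specs <- c(specs,
               list(list(name = paste0(nm, "_vs_genome"), q = sigs[[nm]],
                         bg = genome, alpha = config$enrich_alpha_strict),
                    list(name = paste0(nm, "_vs_UNS"), q = sigs[[nm]],
                         bg = uns_set$members, alpha = config$enrich_alpha_comparison)))
  }
  for (a in names(sigs)) {
    for (b in names(sigs)) {
      if (a == b) next
      specs <- c(specs, list(list(
        name = paste0(a, "_vs_", b),
        q = sigs[[a]],
        bg = union(sigs[[a]]$members, sigs[[b]]$members),
        alpha = config$enrich_alpha_comparison)))
    }
  }
  records <- lapply(specs, function(sp) {
    r <- enrich_terms(sp$q, sp$bg, slim_ann)
    if (nrow(r) == 0L) return(NULL)
    r$comparison <- sp$name
    r$alpha <- sp$alpha
    r$significant <- r$padj < sp$alpha & r$direction == "over"
    r
  })
  records <- do.call(rbind, records)
  # Fig-4-style gene-content percentages per signature over slim terms
  slim_ids <- slim$terms$term
  pct <- sapply(names(sigs), function(nm) {
    m <- sigs[[nm]]$members
    ann <- restrict_annotations(slim_ann, m)
    vapply(slim_ids, function(tm) {
      100 * length(unique(ann$gene[ann$term == tm])) / length(m)
    }, 0)
  })
  pct <- matrix(pct, nrow = length(slim_ids),
                dimnames = list(slim_ids, names(sigs)))
  list(records = records,
       percent_table = pct,
       flagged = records[records$significant, , drop = FALSE])
}
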