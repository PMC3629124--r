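# Pattern-based cluster assignment: each UNS gene is placed in one of seven
# expression clusters from its three pairwise contrasts, and the clusters
# aggregate into the three stage-specific signatures.
#
# Cluster grid (odd = up, even = down in the owning cell type):
#   1 TS-up, 2 TS-down        (blastomere)
#   3 IVVPS-up, 4 IVVPS-down  (ICM)
#   5 IVTPS-up, 6 IVTPS-down  (hESC)
#   7 no significant difference (or conflicting directions)

CLUSTER_SIGNATURE <- c("TS", "TS", "IVVPS", "IVVPS", "IVTPS", "IVTPS", "none")
CLUSTER_OWNER <- c("B", "B", "I", "I", "H", "H", "none")
OWNER_GROUP <- c(B = "blastomere", I = "ICM", H = "hESC")
OWNER_SIG <- c(B = "TS", I = "IVVPS", H = "IVTPS")

# Which cell types each contrast involves, and the sign of each cell type's
# deviation implied by a positive contrast logFC. Contrasts are H-B, H-I,
# I-B, so e.g. a positive H-B logFC means H deviates up and B deviates down.
CONTRAST_INVOLVES <- list(
  "H-B" = c(H = +1, B = -1),
  "H-I" = c(H = +1, I = -1),
  "I-B" = c(I = +1, B = -1)
)

#' Assign UNS genes to expression clusters
#'
#' Decision rule per gene, driven by which of the three pairwise contrasts
#' are significant at `config$de_alpha` (BH-adjusted p by default):
#'
#' 1. No significant contrast: cluster 7.
#' 2. Otherwise each cell type scores the number of significant contrasts it
#'    is involved in; the owner is the top scorer, ties broken by the larger
#'    absolute difference between the cell type's mean and the pooled mean
#'    of the other samples.
#' 3. If the owner's significant contrasts imply conflicting deviation
#'    directions, the gene is flagged ambiguous and placed in cluster 7.
#' 4. Otherwise direction = sign of (owner mean - pooled others mean) and
#'    the gene lands in the owner/direction cell of the six-cluster grid.
#'
#' `mode = "strict"` additionally requires both contrasts involving the
#' owner to be significant; owners failing that go to cluster 7.
#'
#' @param contrasts A `contrast_table` from [contrast_table()].
#' @param uns A [gene_set], character vector or `uns_result` giving the UNS
#'   genes to assign.
#' @param config A [significance_config()].
#' @param mode `"and_or"` (default: one significant contrast can attribute a
#'   gene) or `"strict"` (both of the owner's contrasts must be significant).
#' @return Data frame of class `signature_assignment` with columns `gene`,
#'   `cluster` (1-7), `signature` (TS/IVVPS/IVTPS/none), `direction`
#'   (up/down/none), `owner` (B/I/H/none), `ambiguous`. UNS genes absent
#'   from the contrast table are listed in the `skipped` attribute.
#' @export
assign_clusters <- function(contrasts, uns, config = significance_config(),
                            mode = c("and_or", "strict")) {
  mode <- match.arg(mode)
  members <- if (inherits(uns, "uns_result")) uns$uns$members else as_members(uns)
  assert_that(length(members) > 0L, "UNS gene set is empty")
  idx <- match_ci(members, rownames(contrasts))
  skipped <- members[is.na(idx)]
  members <- members[!is.na(idx)]
  idx <- idx[!is.na(idx)]

  group_n <- attr(contrasts, "group_n")
  means <- as.matrix(contrasts[idx, c("mean_blastomere", "mean_ICM", "mean_hESC")])
  colnames(means) <- c("B", "I", "H")
  if (is.null(group_n)) group_n <- c(1, 1, 1)
  sig <- as.matrix(contrasts[idx, c("sig_H.B", "sig_H.I", "sig_I.B")])
  lfc <- as.matrix(contrasts[idx, c("logFC_H.B", "logFC_H.I", "logFC_I.B")])
  colnames(sig) <- colnames(lfc) <- names(CONTRAST_INVOLVES)

  n_by <- c(B = group_n[1L], I = group_n[2L], H = group_n[3L])
  total_n <- sum(n_by)
  # pooled mean of the other two groups, sample-weighted
  pooled_others <- vapply(c("B", "I", "H"), function(X) {
    as.numeric(means %*% n_by - means[, X] * n_by[[X]]) / (total_n - n_by[[X]])
  }, numeric(length(idx)))
  pooled_others <- matrix(pooled_others, ncol = 3L,
                          dimnames = list(NULL, c("B", "I", "H")))

  out <- data.frame(gene = members, cluster = 7L, signature = "none",
                    direction = "none", owner = "none", ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(members)) {
    sig_i <- sig[i, ]
    if (!any(sig_i)) next
    score <- c(B = 0L, I = 0L, H = 0L)
    dev_signs <- list(B = numeric(0), I = numeric(0), H = numeric(0))
    for (ct in names(CONTRAST_INVOLVES)) {
      if (!sig_i[[ct]]) next
      inv <- CONTRAST_INVOLVES[[ct]]
      for (X in names(inv)) {
        score[[X]] <- score[[X]] + 1L
        dev_signs[[X]] <- c(dev_signs[[X]], inv[[X]] * sign(lfc[i, ct]))
      }
    }
    top <- names(score)[score == max(score)]
    if (length(top) > 1L) {
      eff <- abs(means[i, top] - pooled_others[i, top])
      top <- top[which.max(eff)]
    }
    if (mode == "strict" && score[[top]] < 2L) next
    signs <- dev_signs[[top]]
    if (length(unique(signs)) > 1L) {
      out$ambiguous[i] <- TRUE
      next
    }
    dir <- if (means[i, top] - pooled_others[i, top] > 0) "up" else "down"
    out$owner[i] <- top
    out$signature[i] <- OWNER_SIG[[top]]
    out$direction[i] <- dir
    out$cluster[i] <- cluster_of(out$signature[i], dir)
  }
  structure(out, skipped = skipped,
            class = c("signature_assignment", "data.frame"))
}

#' Summarize signature sizes and connector content
#'
#' Per-signature totals, up/down splits with nearest-integer percentages,
#' and (when a `uns_result` is supplied) connector counts and fractions.
#' Asserts the partition invariant |TS| + |IVVPS| + |IVTPS| + |cluster 7|
#' = |assigned UNS genes|.
#'
#' @param assignment A `signature_assignment` from [assign_clusters()].
#' @param uns Optional `uns_result`; enables the connector columns.
#' @return Data frame with one row per signature (TS, IVVPS, IVTPS):
#'   `n_total`, `n_up`, `n_down`, `pct_up`, `pct_down`, `connector_count`,
#'   `connector_fraction`; attribute `n_cluster7` carries the
#'   no-significant-difference count.
#' @export
summarize_signatures <- function(assignment, uns = NULL) {
  stopifnot(inherits(assignment, "signature_assignment"))
  connectors <- if (!is.null(uns)) uns$connectors$members else character(0)
  rows <- lapply(SIGNATURES, function(s) {
    in_sig <- assignment$signature == s
    n_up <- sum(in_sig & assignment$direction == "up")
    n_down <- sum(in_sig & assignment$direction == "down")
    n_total <- n_up + n_down
    conn <- sum(assignment$gene[in_sig] %in_ci% connectors)
    data.frame(signature = s, n_total = n_total, n_up = n_up, n_down = n_down,
               pct_up = if (n_total) as.integer(round(100 * n_up / n_total)) else 0L,
               pct_down = if (n_total) as.integer(round(100 * n_down / n_total)) else 0L,
               connector_count = conn,
               connector_fraction = if (n_total) conn / n_total else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n7 <- sum(assignment$cluster == 7L)
  assert_that(sum(out$n_total) + n7 == nrow(assignment),
              "internal error: clusters do not partition the UNS")
  structure(out, n_cluster7 = n7)
}

#' Export signature gene sets
#'
#' @param assignment A `signature_assignment`.
#' @return Named list of [gene_set]s (TS, IVVPS, IVTPS; empty signatures are
#'   dropped).
#' @export
signature_gene_sets <- function(assignment) {
  sets <- list()
  for (s in SIGNATURES) {
    m <- assignment$gene[assignment$signature == s]
    if (length(m)) sets[[s]] <- gene_set(s, m, sprintf("%s signature genes", s))
  }
  sets
}
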