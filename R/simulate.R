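# Synthetic-data generator: expression matrices, interaction networks, seed
# lists and GO annotations with the statistical structure the analysis
# assumes, plus ground truth for recovery tests.
#
# The default configuration mirrors the study design the pipeline targets:
# 41 single blastomeres, 2 inner cell masses, 5 hESC lines; a 191-gene
# curated seed list expanded by 75 network connectors into a 266-gene UNS;
# and planted stage-specific signatures of 61 (17 up / 44 down, blastomere),
# 21 (17 up / 4 down, ICM) and 107 (83 up / 24 down, hESC) genes.

SIGNATURES <- c("TS", "IVVPS", "IVTPS")
SIG_GROUP <- c(TS = "blastomere", IVVPS = "ICM", IVTPS = "hESC")
GROUP_LEVELS <- c("blastomere", "ICM", "hESC")
COMPARTMENTS <- c("nucleus", "cytoplasm", "plasma membrane", "extracellular space")

# cluster grid: odd = up, even = down; 1/2 TS, 3/4 IVVPS, 5/6 IVTPS, 7 none
cluster_of <- function(signature, direction) {
  base <- c(TS = 0L, IVVPS = 2L, IVTPS = 4L)[signature]
  base + ifelse(direction == "up", 1L, 2L)
}

#' Simulation configuration
#'
#' Defines the study design emulated by the generators: group sizes, gene
#' universe, seed-list and connector sizes, the per-signature planted
#' up/down-regulated gene counts, the log2 effect size and residual noise.
#'
#' @param n_blastomere,n_icm,n_hesc Samples per group (defaults 41, 2, 5).
#'   `n_icm` must be at least 2 so a within-group variance exists.
#' @param n_genes Size of the gene universe (default 2000).
#' @param n_seed Size of the curated seed list (default 191).
#' @param n_connector_true Number of genes wired as true network connectors
#'   (default 75).
#' @param planted Named list `list(TS = c(up=, down=), IVVPS = ..., IVTPS = ...)`
#'   of planted signature sizes; totals must fit inside the
#'   `n_seed + n_connector_true` gene pool.
#' @param effect_size Log2 shift applied to a planted gene in its owning
#'   group (default 3.0); `0` gives a null simulation.
#' @param noise_sd Residual s.d. of log2 intensities (default 0.5).
#' @param baseline_mean Log2 baseline intensity (default 8.0).
#' @param p_in,p_out Annotation probabilities for the planted enriched GO
#'   term inside / outside its target signature (defaults 0.6, 0.08).
#' @param enriched_signature Signature carrying the planted enriched term
#'   (default `"IVTPS"`).
#' @param rng_seed Integer seed driving all three generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_blastomere = 41L, n_icm = 2L, n_hesc = 5L,
                       n_genes = 2000L, n_seed = 191L, n_connector_true = 75L,
                       planted = list(TS = c(up = 17L, down = 44L),
                                      IVVPS = c(up = 17L, down = 4L),
                                      IVTPS = c(up = 83L, down = 24L)),
                       effect_size = 3.0, noise_sd = 0.5, baseline_mean = 8.0,
                       p_in = 0.6, p_out = 0.08,
                       enriched_signature = "IVTPS",
                       rng_seed = 1L) {
  assert_that(n_blastomere >= 1L && n_hesc >= 1L, "group sizes must be >= 1")
  assert_that(n_icm >= 2L, "n_icm must be >= 2 (within-group variance must be estimable)")
  assert_that(n_genes >= 1L && n_seed >= 1L && n_connector_true >= 0L,
              "gene counts must be non-negative (n_genes, n_seed >= 1)")
  assert_that(setequal(names(planted), SIGNATURES),
              "planted must name TS, IVVPS and IVTPS")
  planted <- lapply(planted, function(p) {
    assert_that(all(c("up", "down") %in% names(p)) && all(p >= 0),
                "each planted entry needs non-negative 'up' and 'down' counts")
    c(up = as.integer(p[["up"]]), down = as.integer(p[["down"]]))
  })[SIGNATURES]
  n_planted <- sum(unlist(planted))
  pool <- n_seed + n_connector_true
  assert_that(n_planted <= pool,
              sprintf("planted totals (%d) exceed the seed + connector pool (%d)",
                      n_planted, pool))
  assert_that(pool <= n_genes,
              sprintf("seed + connector pool (%d) exceeds n_genes (%d)", pool, n_genes))
  assert_that(effect_size >= 0, "effect_size must be >= 0 (0 = null simulation)")
  assert_that(noise_sd > 0, "noise_sd must be > 0")
  assert_that(p_in > 0 && p_in <= 1 && p_out > 0 && p_out <= 1,
              "annotation probabilities must lie in (0, 1]")
  assert_that(enriched_signature %in% SIGNATURES, "unknown enriched_signature")
  structure(list(n_blastomere = as.integer(n_blastomere),
                 n_icm = as.integer(n_icm), n_hesc = as.integer(n_hesc),
                 n_genes = as.integer(n_genes), n_seed = as.integer(n_seed),
                 n_connector_true = as.integer(n_connector_true),
                 planted = planted, effect_size = effect_size,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 p_in = p_in, p_out = p_out,
                 enriched_signature = enriched_signature,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# Synthetic symbols G000001... with a reserved alias slot so well-known marker
# names can be injected into fixtures without touching annotation databases.
gene_symbols <- function(n, aliases = character(0)) {
  sym <- sprintf("G%06d", seq_len(n))
  if (length(aliases)) sym[seq_along(aliases)] <- aliases
  sym
}

# Ground-truth table shared by the three generators: seed genes first, then
# connectors, then background; planted signature genes are drawn from a
# seeded shuffle of the seed+connector pool.
build_truth <- function(config) {
  genes <- gene_symbols(config$n_genes)
  is_seed <- seq_len(config$n_genes) <= config$n_seed
  is_connector <- seq_len(config$n_genes) > config$n_seed &
    seq_len(config$n_genes) <= config$n_seed + config$n_connector_true
  truth <- data.frame(gene = genes,
                      true_cluster = 7L,
                      true_signature = "none",
                      direction = "none",
                      is_seed = is_seed,
                      is_connector = is_connector,
                      stringsAsFactors = FALSE)
  pool <- sample(which(is_seed | is_connector))
  at <- 0L
  for (sig in SIGNATURES) {
    for (dir in c("up", "down")) {
      k <- config$planted[[sig]][[dir]]
      if (k == 0L) next
      idx <- pool[at + seq_len(k)]
      at <- at + k
      truth$true_signature[idx] <- sig
      truth$direction[idx] <- dir
      truth$true_cluster[idx] <- cluster_of(sig, dir)
    }
  }
  truth
}

#' Simulate a three-group expression matrix with planted signatures
#'
#' Generates log2 intensities for `n_genes` genes over the
#' blastomere/ICM/hESC design. A gene planted "up" in its signature's cell
#' type has mean `baseline_mean + effect_size` in that group and
#' `baseline_mean` elsewhere (planted "down": minus); unplanted genes share
#' one mean across groups. Residuals are i.i.d. Gaussian with s.d.
#' `noise_sd`. Fully reproducible from `rng_seed`.
#'
#' @param config A [sim_config()].
#' @return List with `exprs` (genes x samples log2 matrix), `groups` (named
#'   factor with levels blastomere, ICM, hESC), and `truth` (ground-truth
#'   data frame: gene, true_cluster, true_signature, direction, is_seed,
#'   is_connector).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, {
    truth <- build_truth(config)
    n_s <- c(config$n_blastomere, config$n_icm, config$n_hesc)
    groups <- factor(rep(GROUP_LEVELS, n_s), levels = GROUP_LEVELS)
    samples <- c(sprintf("B%02d", seq_len(n_s[1L])),
                 sprintf("I%02d", seq_len(n_s[2L])),
                 sprintf("H%02d", seq_len(n_s[3L])))
    names(groups) <- samples
    mu <- matrix(config$baseline_mean, nrow = config$n_genes, ncol = sum(n_s),
                 dimnames = list(truth$gene, samples))
    shift <- ifelse(truth$direction == "up", config$effect_size,
                    ifelse(truth$direction == "down", -config$effect_size, 0))
    for (sig in SIGNATURES) {
      in_sig <- truth$true_signature == sig
      in_grp <- groups == SIG_GROUP[[sig]]
      mu[in_sig, in_grp] <- mu[in_sig, in_grp] + shift[in_sig]
    }
    exprs <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                         nrow = nrow(mu))
    dimnames(exprs) <- dimnames(mu)
    list(exprs = exprs, groups = groups, truth = truth)
  })
}

#' Simulate an interaction network with planted connectors
#'
#' Wires each designated true connector to at least `k_min` (15 by default)
#' distinct seed genes and every non-connector background gene to fewer than
#' `k_min`, so that connector selection at the threshold recovers exactly the
#' planted set. Adds random seed-seed edges, typed edge labels
#' (physical / biochemical / functional) and node compartment and function
#' attributes. Reproducible from `rng_seed`.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth table from [simulate_expression()].
#' @param k_min Connector threshold the construction separates at (default 15).
#' @return An undirected [igraph::igraph] with edge attribute `type` and
#'   vertex attributes `compartment`, `general_function`, `specific_function`.
#' @export
simulate_network <- function(config, truth, k_min = 15L) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(config$n_seed >= k_min,
              sprintf("n_seed (%d) < k_min (%d): no connector can exist",
                      config$n_seed, k_min))
  with_seed(config$rng_seed + 1L, {
    seed_genes <- truth$gene[truth$is_seed]
    connectors <- truth$gene[truth$is_connector]
    background <- truth$gene[!truth$is_seed & !truth$is_connector]
    from <- character(0); to <- character(0)
    # connectors: k_min .. k_min+10 distinct seed partners
    for (g in connectors) {
      k <- k_min + sample.int(11L, 1L) - 1L
      nb <- sample(seed_genes, min(k, length(seed_genes)))
      from <- c(from, rep(g, length(nb))); to <- c(to, nb)
    }
    # background genes: sparse attachment, capped strictly below the threshold
    cap <- min(k_min - 1L, length(seed_genes))
    n_bg <- pmin(stats::rpois(length(background), 2), cap)
    for (i in seq_along(background)) {
      if (n_bg[i] == 0L) next
      nb <- sample(seed_genes, n_bg[i])
      from <- c(from, rep(background[i], n_bg[i])); to <- c(to, nb)
    }
    # seed-seed edges for realism (do not affect connector status)
    n_ss <- min(2L * length(seed_genes), choose(length(seed_genes), 2))
    if (n_ss > 0L && length(seed_genes) >= 2L) {
      a <- sample(seed_genes, n_ss, replace = TRUE)
      b <- sample(seed_genes, n_ss, replace = TRUE)
      ok <- a != b
      from <- c(from, a[ok]); to <- c(to, b[ok])
    }
    type <- sample(c("physical", "biochemical", "functional"),
                   length(from), replace = TRUE,
                   prob = c(0.4, 0.2, 0.4))
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, type = type, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = truth$gene, stringsAsFactors = FALSE))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = list(type = merge_edge_types))
    igraph::V(g)$compartment <- sample(COMPARTMENTS, igraph::vcount(g),
                                       replace = TRUE,
                                       prob = c(0.4, 0.3, 0.2, 0.1))
    igraph::V(g)$general_function <- sample(
      c("transcription factor", "signaling", "structural", "enzyme", "transport"),
      igraph::vcount(g), replace = TRUE)
    igraph::V(g)$specific_function <- sample(
      c("cell cycle", "adhesion", "metabolism", "proliferation", "methylation",
        "translation"),
      igraph::vcount(g), replace = TRUE)
    g
  })
}

#' Simulate gene-to-term annotations and a GO-slim vocabulary
#'
#' Builds a 33-term slim vocabulary, a set of fine-grained child terms each
#' mapped to one slim ancestor, and a gene-to-child-term annotation table in
#' which one designated child term annotates genes of the chosen planted
#' signature with probability `p_in` and all other gene-term pairs occur with
#' probability `p_out`. Reproducible from `rng_seed`.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth table from [simulate_expression()].
#' @param n_slim Number of slim terms (default 33).
#' @param children_per_slim Fine-grained child terms per slim term (default 3).
#' @return List with `annotations` (data frame gene, term), `slim` (list with
#'   `terms` data frame term/name and `ancestors` data frame term/ancestor),
#'   and `enriched_term` (the planted child term ID).
#' @export
simulate_annotations <- function(config, truth, n_slim = 33L,
                                 children_per_slim = 3L) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(n_slim >= 1L, "slim vocabulary must be non-empty")
  with_seed(config$rng_seed + 2L, {
    slim_terms <- sprintf("SLIM:%04d", seq_len(n_slim))
    slim_names <- sprintf("slim category %d", seq_len(n_slim))
    n_child <- n_slim * children_per_slim
    child_terms <- sprintf("GO:%07d", seq_len(n_child))
    ancestors <- data.frame(term = child_terms,
                            ancestor = rep(slim_terms, each = children_per_slim),
                            stringsAsFactors = FALSE)
    enriched_term <- child_terms[1L]
    in_sig <- truth$true_signature == config$enriched_signature
    prob <- matrix(config$p_out, nrow = nrow(truth), ncol = n_child)
    prob[in_sig, 1L] <- config$p_in
    hit <- matrix(stats::runif(length(prob)) < prob, nrow = nrow(prob))
    idx <- which(hit, arr.ind = TRUE)
    annotations <- data.frame(gene = truth$gene[idx[, 1L]],
                              term = child_terms[idx[, 2L]],
                              stringsAsFactors = FALSE)
    annotations <- annotations[order(annotations$gene, annotations$term), ]
    rownames(annotations) <- NULL
    list(annotations = annotations,
         slim = list(terms = data.frame(term = slim_terms, name = slim_names,
                                        stringsAsFactors = FALSE),
                     ancestors = ancestors),
         enriched_term = enriched_term)
  })
}

#' Simulate raw scanner-scale intensities
#'
#' Additive background model for exercising the normexp background
#' correction: observed intensity = Normal(`mu`, `sigma`^2) background +
#' Exponential(mean `alpha`) signal.
#'
#' @param n Number of values.
#' @param mu,sigma Background mean and s.d.
#' @param alpha Signal exponential mean.
#' @param rng_seed Optional seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_raw_intensities <- function(n, mu = 100, sigma = 10, alpha = 500,
                                     rng_seed = NULL) {
  assert_that(sigma > 0 && alpha > 0, "sigma and alpha must be > 0")
  with_seed(rng_seed,
            stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / alpha))
}
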