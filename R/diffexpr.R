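# Three-group moderated differential expression: per-gene one-way linear
# model (group means + pooled residual variance), empirical-Bayes variance
# shrinkage toward a prior estimated by moment matching on log variances,
# moderated t-statistics for the three pairwise contrasts, and
# Benjamini-Hochberg adjustment.
#
# The hierarchical model: s2_g | sigma2_g ~ sigma2_g * chi2_{d_g} / d_g and
# 1/sigma2_g ~ (1/(d0*s0^2)) * chi2_{d0}. The posterior variance
# s2_post = (d0*s0^2 + d_g*s2_g) / (d0 + d_g) replaces s2_g in the t
# statistic, whose null distribution gains d0 extra degrees of freedom.

CONTRASTS <- c("H-B", "H-I", "I-B")

#' Significance configuration
#'
#' Thresholds used across the pipeline: `de_alpha` for calling a contrast
#' significant in the cluster assignment (default 0.05, applied to
#' BH-adjusted p by default), `enrich_alpha_strict` for the
#' signature-versus-genome enrichment (default 0.005), and
#' `enrich_alpha_comparison` for the between-signature comparisons
#' (default 0.1).
#'
#' @param de_alpha Differential-expression cutoff in (0,1).
#' @param enrich_alpha_strict Strict enrichment cutoff in (0,1).
#' @param enrich_alpha_comparison Comparison-battery cutoff in (0,1).
#' @param use_adjusted Apply `de_alpha` to BH-adjusted p (`TRUE`, default)
#'   or raw p.
#' @return A `significance_config` list.
#' @export
significance_config <- function(de_alpha = 0.05, enrich_alpha_strict = 0.005,
                                enrich_alpha_comparison = 0.1,
                                use_adjusted = TRUE) {
  for (a in c(de_alpha, enrich_alpha_strict, enrich_alpha_comparison)) {
    assert_that(a > 0 && a < 1, "alpha thresholds must lie in (0, 1)")
  }
  structure(list(de_alpha = de_alpha,
                 enrich_alpha_strict = enrich_alpha_strict,
                 enrich_alpha_comparison = enrich_alpha_comparison,
                 use_adjusted = isTRUE(use_adjusted)),
            class = "significance_config")
}

#' Fit per-gene group means and pooled residual variance
#'
#' One-way three-group linear model fitted gene-wise: group means, pooled
#' within-group residual variance `s2` and residual degrees of freedom
#' `df = N - 3`. A group with a single sample contributes its mean but no
#' residual degrees of freedom; genes with zero residual variance are kept
#' (they are shrunk later).
#'
#' @param matrix Numeric genes x samples matrix.
#' @param groups Factor of length `ncol(matrix)` with exactly 3 levels, each
#'   represented by at least one sample; at least 4 samples overall.
#' @return List of class `gene_fit`: `means` (genes x 3), `s2`, `df`, `n`
#'   (samples per group), `levels`.
#' @export
fit_groups <- function(matrix, groups) {
  groups <- as.factor(groups)
  assert_that(nlevels(droplevels(groups)) == 3L,
              "fit_groups expects exactly 3 group labels")
  groups <- droplevels(groups)
  assert_that(length(groups) == ncol(matrix),
              "groups must have one label per sample column")
  n <- table(groups)
  assert_that(all(n >= 1L), "every group needs at least one sample")
  N <- ncol(matrix)
  assert_that(N >= 4L, "need at least 4 samples for a residual degree of freedom")
  ind <- stats::model.matrix(~ 0 + groups)  # samples x 3 indicator
  means <- matrix %*% ind %*% diag(1 / as.numeric(n))
  colnames(means) <- levels(groups)
  fitted <- means %*% t(ind)
  rss <- rowSums((matrix - fitted)^2)
  df <- N - 3L
  structure(list(means = means, s2 = rss / df, df = df,
                 n = as.numeric(n), levels = levels(groups)),
            class = "gene_fit")
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing, convex).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, 0)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching on log sample variances (Smyth-style): under the
#' hierarchical model, e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2) has mean
#' log(s0^2) + digamma(d0/2) - log(d0/2) and variance
#' trigamma(d_g/2) + trigamma(d0/2). The empirical excess variance of e_g
#' over trigamma(d_g/2) is inverted through the trigamma function to give
#' `d0`; the mean equation then gives `s0_sq`. Zero excess (e.g. identical
#' variances) yields `d0 = Inf` with every posterior variance equal to
#' `s0_sq`; that limit is a documented outcome, not an error.
#'
#' @param fits A `gene_fit` from [fit_groups()] (>= 50 genes with positive
#'   residual df). Genes with `s2 == 0` are excluded from prior estimation
#'   but still shrunk by the posterior formula.
#' @return List of class `ebayes_params` with `d0` (prior df, possibly
#'   `Inf`), `s0_sq` (prior variance) and `s2_post` (posterior variances,
#'   one per gene).
#' @export
ebayes_shrink <- function(fits) {
  stopifnot(inherits(fits, "gene_fit"))
  assert_that(fits$df > 0L, "no residual degrees of freedom to shrink")
  s2 <- fits$s2
  ok <- is.finite(s2) & s2 > 0
  assert_that(sum(ok) >= 50L, "ebayes_shrink needs >= 50 genes with positive variance")
  dg <- fits$df
  e <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1L) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion: infinite prior df, prior = geometric mean of the
    # observed variances (equal to the common value when all are identical)
    d0 <- Inf
    s0_sq <- exp(mean(log(s2[ok])))
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  names(s2_post) <- names(s2)
  structure(list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post),
            class = "ebayes_params")
}

# Parse "H-B" style contrast labels against the canonical level names.
contrast_levels <- function(contrast, levels) {
  code <- c(B = "blastomere", I = "ICM", H = "hESC")
  assert_that(contrast %in% CONTRASTS,
              sprintf("contrast must be one of %s", paste(CONTRASTS, collapse = ", ")))
  parts <- strsplit(contrast, "-", fixed = TRUE)[[1L]]
  lv <- code[parts]
  assert_that(all(lv %in% levels),
              "group levels must be blastomere, ICM, hESC to use named contrasts")
  lv
}

#' Moderated t-statistics for a pairwise contrast
#'
#' t_g = (mean_A - mean_B) / (s_post_g * sqrt(1/n_A + 1/n_B)), with two-sided
#' p-values from the t distribution on `d0 + df` degrees of freedom
#' (the normal when `d0` is infinite). A zero posterior variance gives an
#' infinite t and p = 0, with a warning.
#'
#' @param fits A `gene_fit` from [fit_groups()].
#' @param params An `ebayes_params` from [ebayes_shrink()]; pass
#'   `d0 = 0` semantics by constructing params with `s2_post = fits$s2`.
#' @param contrast One of `"H-B"`, `"H-I"`, `"I-B"` (hESC, blastomere, ICM).
#' @return Data frame with `logFC`, `t`, `p` per gene.
#' @export
moderated_t <- function(fits, params, contrast) {
  stopifnot(inherits(fits, "gene_fit"))
  lv <- contrast_levels(contrast, fits$levels)
  iA <- match(lv[1L], fits$levels); iB <- match(lv[2L], fits$levels)
  logFC <- fits$means[, iA] - fits$means[, iB]
  se <- sqrt(params$s2_post * (1 / fits$n[iA] + 1 / fits$n[iB]))
  t <- logFC / se
  if (any(se == 0)) {
    warning(sprintf("%d gene(s) with zero posterior variance: t infinite, p = 0",
                    sum(se == 0)))
    t[se == 0] <- sign(logFC[se == 0]) * Inf
    t[se == 0 & logFC == 0] <- 0
  }
  df_total <- params$d0 + fits$df
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[is.infinite(t)] <- 0
  data.frame(logFC = logFC, t = t, p = p, row.names = rownames(fits$means))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust]), with
#' input validation: values must lie in [0, 1].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values, same order as the input; each adjusted value
#'   is >= its raw value and the ordering of p-values is preserved.
#' @export
bh_adjust <- function(pvalues) {
  assert_that(all(is.finite(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Full three-contrast moderated differential expression
#'
#' Fits the three-group model, shrinks variances, computes moderated t and
#' two-sided p for the contrasts hESC-blastomere, hESC-ICM and
#' ICM-blastomere, and BH-adjusts p-values within each contrast.
#'
#' @param matrix Numeric genes x samples log2 matrix.
#' @param groups Factor with levels blastomere, ICM, hESC.
#' @param config A [significance_config()].
#' @return Data frame of class `contrast_table` with one row per gene:
#'   `mean_blastomere`, `mean_ICM`, `mean_hESC`, then per contrast `c` in
#'   `H.B`, `H.I`, `I.B` the columns `logFC_c`, `t_c`, `p_c`, `padj_c`,
#'   `sig_c`. Attributes `d0`, `s0_sq`, `group_n` record the shrinkage fit.
#' @export
contrast_table <- function(matrix, groups, config = significance_config()) {
  fits <- fit_groups(matrix, groups)
  params <- ebayes_shrink(fits)
  out <- data.frame(row.names = rownames(matrix))
  for (lv in fits$levels) {
    out[[paste0("mean_", lv)]] <- fits$means[, lv]
  }
  for (ct in CONTRASTS) {
    res <- moderated_t(fits, params, ct)
    padj <- bh_adjust(res$p)
    pp <- if (config$use_adjusted) padj else res$p
    tag <- gsub("-", ".", ct, fixed = TRUE)
    out[[paste0("logFC_", tag)]] <- res$logFC
    out[[paste0("t_", tag)]] <- res$t
    out[[paste0("p_", tag)]] <- res$p
    out[[paste0("padj_", tag)]] <- padj
    out[[paste0("sig_", tag)]] <- pp < config$de_alpha
  }
  structure(out, d0 = params$d0, s0_sq = params$s0_sq, group_n = fits$n,
            class = c("contrast_table", "data.frame"))
}
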