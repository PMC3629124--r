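# Background correction, quantile normalization, log transform and PCA.
#
# The normexp convolution model treats an observed intensity as
# X = B + S with background B ~ Normal(mu, sigma^2) and signal
# S ~ Exponential(mean alpha). Fitting maximizes the convolution likelihood;
# correction returns E[S | X = x], which is strictly positive, so corrected
# intensities can always be log-transformed.

# log density of the normal + exponential convolution, numerically stable via
# pnorm(log.p = TRUE) for the Mills-ratio tail.
normexp_loglik <- function(x, mu, sigma, alpha) {
  z <- (x - mu - sigma^2 / alpha) / sigma
  sum(-log(alpha) + (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
        stats::pnorm(z, log.p = TRUE))
}

#' Fit the normexp background model
#'
#' Maximum-likelihood fit of the convolution X = B + S,
#' B ~ Normal(`mu`, `sigma`^2), S ~ Exponential(mean `alpha`), by BFGS over
#' (`mu`, log `sigma`, log `alpha`) from method-of-moments starting values.
#'
#' @param intensities Numeric vector of raw intensities (>= 10 finite values;
#'   a constant vector is rejected as degenerate).
#' @return List of class `normexp_params` with `mu`, `sigma`, `alpha`, and
#'   the achieved `loglik`.
#' @export
normexp_fit <- function(intensities) {
  x <- intensities[is.finite(intensities)]
  assert_that(length(x) >= 10L, "normexp_fit needs at least 10 finite values")
  assert_that(stats::sd(x) > 0, "normexp_fit: constant input is degenerate")
  # moments: E[X] = mu + alpha, Var[X] = sigma^2 + alpha^2
  q05 <- stats::quantile(x, 0.05, names = FALSE)
  alpha0 <- max(mean(x) - q05, stats::sd(x) / 10)
  sigma0 <- sqrt(max(stats::var(x) - alpha0^2, (alpha0 / 10)^2))
  mu0 <- mean(x) - alpha0
  nll <- function(par) {
    -normexp_loglik(x, par[1L], exp(par[2L]), exp(par[3L]))
  }
  fit <- stats::optim(c(mu0, log(sigma0), log(alpha0)), nll, method = "BFGS",
                      control = list(maxit = 500))
  structure(list(mu = fit$par[1L], sigma = exp(fit$par[2L]),
                 alpha = exp(fit$par[3L]), loglik = -fit$value),
            class = "normexp_params")
}

#' Background-correct intensities under a fitted normexp model
#'
#' Returns the posterior mean signal E[S | X = x] in closed form:
#' with m = x - mu - sigma^2/alpha, the conditional mean is
#' m + sigma * phi(m/sigma) / Phi(m/sigma), evaluated on the log scale for
#' stability. The result is strictly positive and monotone increasing in x.
#'
#' @param x Numeric vector of observed intensities (finite).
#' @param params A `normexp_params` object (or list with `mu`, `sigma`,
#'   `alpha`).
#' @return Corrected intensities, same length as `x`.
#' @export
normexp_adjust <- function(x, params) {
  assert_that(all(is.finite(x)), "normexp_adjust: x must be finite")
  assert_that(params$sigma > 0 && params$alpha > 0,
              "normexp params need sigma > 0 and alpha > 0")
  m <- x - params$mu - params$sigma^2 / params$alpha
  z <- m / params$sigma
  m + params$sigma * exp(stats::dnorm(z, log = TRUE) -
                           stats::pnorm(z, log.p = TRUE))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the common target distribution given by
#' the across-sample mean of order statistics, preserving within-column rank
#' order. Ties within a column receive the mean of the target values their
#' rank span covers, which makes the operation deterministic and invariant
#' to row permutation.
#'
#' @param matrix Numeric genes x samples matrix, >= 2 columns, no missing
#'   values (impute before normalizing).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  assert_that(is.matrix(matrix) && ncol(matrix) >= 2L,
              "quantile_normalize needs a matrix with >= 2 samples")
  assert_that(!anyNA(matrix),
              "missing values present: impute before quantile normalization")
  target <- rowMeans(apply(matrix, 2L, sort))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    if (all(lo == hi)) {
      out[, j] <- target[lo]
    } else {
      csum <- cumsum(target)
      # mean of target[lo..hi] for each value's tie span
      out[, j] <- (csum[hi] - csum[lo] + target[lo]) / (hi - lo + 1)
    }
  }
  out
}

#' Principal component analysis of samples
#'
#' Samples are observations and genes variables; genes are mean-centred but
#' not scaled to unit variance (the standard convention for log-expression
#' PCA). Components come from the singular value decomposition; the variance
#' fraction of component k is its eigenvalue over the eigenvalue total.
#'
#' @param matrix Numeric genes x samples matrix with >= 2 samples.
#' @param gene_subset Optional [gene_set] or character vector restricting the
#'   analysis to those genes (matched case-insensitively); at least 2 must be
#'   present.
#' @return List of class `ordination` with `scores` (samples x components)
#'   and `variance_fraction` (non-increasing, sums to 1).
#' @export
pca_expr <- function(matrix, gene_subset = NULL) {
  assert_that(is.matrix(matrix) && ncol(matrix) >= 2L,
              "pca_expr needs a matrix with >= 2 samples")
  if (!is.null(gene_subset)) {
    members <- as_members(gene_subset)
    keep <- rownames(matrix) %in_ci% members
    assert_that(sum(keep) >= 2L,
                "gene subset shares fewer than 2 genes with the matrix")
    matrix <- matrix[keep, , drop = FALSE]
  }
  p <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  structure(list(scores = p$x, variance_fraction = ev / sum(ev)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat("<ordination>", nrow(x$scores), "samples\n")
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
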