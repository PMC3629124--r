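# Background correction, quantile normalization and PCA.

test_that("normexp_fit recovers generating parameters and rejects degenerate input", {
  x <- simulate_raw_intensities(20000, mu = 100, sigma = 10, alpha = 500,
                                rng_seed = 42L)
  fit <- normexp_fit(x)
  expect_equal(fit$mu, 100, tolerance = 0.05)
  expect_equal(fit$sigma, 10, tolerance = 0.10)
  expect_equal(fit$alpha, 500, tolerance = 0.05)
  # fitted likelihood at least matches the truth's
  expect_gte(fit$loglik, stemsig:::normexp_loglik(x, 100, 10, 500) - 1e-6)
  expect_error(normexp_fit(rep(5, 100)), "constant")
  expect_error(normexp_fit(c(1, 2, 3)), "10")
})

test_that("normexp_fit agrees with the reference MLE fit", {
  skip_if_not_installed("limma")
  x <- simulate_raw_intensities(20000, mu = 80, sigma = 15, alpha = 300,
                                rng_seed = 9L)
  ours <- normexp_fit(x)
  ref <- limma::normexp.fit(matrix(x, ncol = 1), method = "mle")$par
  expect_equal(ours$mu, ref[1L], tolerance = 0.01)
  expect_equal(ours$sigma, exp(ref[2L]), tolerance = 0.02)
  expect_equal(ours$alpha, exp(ref[3L]), tolerance = 0.01)
})

test_that("normexp_adjust matches the quadrature oracle and its limits", {
  params <- list(mu = 50, sigma = 10, alpha = 200)
  x <- 300
  # E[S | X = x] by numeric integration of the conditional density
  joint <- function(s) stats::dexp(s, 1 / params$alpha) *
    stats::dnorm(x - s, params$mu, params$sigma)
  upper <- x + 20 * params$sigma
  num <- stats::integrate(function(s) s * joint(s), 0, upper,
                          rel.tol = 1e-10, subdivisions = 2000L)$value
  den <- stats::integrate(joint, 0, upper, rel.tol = 1e-10,
                          subdivisions = 2000L)$value
  expect_equal(normexp_adjust(x, params), num / den, tolerance = 1e-6)

  # vanishing background: corrected value tends to x - mu
  expect_equal(normexp_adjust(100, list(mu = 0, sigma = 1e-8, alpha = 200)),
               100, tolerance = 1e-4)
  # positivity even far below the background mean
  xs <- seq(-200, 400, by = 10)
  out <- normexp_adjust(xs, params)
  expect_true(all(out > 0))
  # monotone increasing in x
  expect_true(all(diff(out) > 0))
})

test_that("quantile normalization equalizes columns with the rank-mean rule", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 3, 5))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5, 5.5))

  # identical columns are a fixed point
  m2 <- cbind(c(1, 7, 3), c(1, 7, 3))
  expect_equal(quantile_normalize(m2), m2)

  # idempotence and exact column-distribution equality on continuous data
  set.seed(1)
  r <- matrix(rnorm(60), 12, 5)
  q1 <- quantile_normalize(r)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  sorted <- apply(q1, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # rank order within each column preserved
  for (j in 1:5) expect_equal(order(q1[, j]), order(r[, j]))

  # ties receive the mean of the target values their span covers
  mt <- cbind(c(1, 1, 5), c(2, 4, 6))
  target <- rowMeans(cbind(sort(mt[, 1]), sort(mt[, 2])))
  out <- quantile_normalize(mt)
  expect_equal(unname(out[, 1]), c(mean(target[1:2]), mean(target[1:2]), target[3]))

  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "impute")
})

test_that("quantile normalization matches the independent rank-mean oracle", {
  set.seed(2)
  for (i in 1:20) {
    m <- matrix(rnorm(25), 5, 5)
    expect_equal(unname(quantile_normalize(m)), unname(qn_oracle(m)),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("limma")
  m <- matrix(rnorm(200), 40, 5)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
})

test_that("PCA variance fractions behave as stated", {
  # samples on a line in gene space: PC1 carries all variance
  base <- rnorm(10)
  m <- sapply(seq(0, 1, length.out = 6), function(t) base + t * rep(1, 10))
  rownames(m) <- paste0("g", 1:10)
  p <- pca_expr(m)
  expect_equal(p$variance_fraction[1L], 1, tolerance = 1e-10)

  set.seed(3)
  m <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("g", 1:20), NULL))
  p <- pca_expr(m)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))

  # gene-wise mean shifts do not change scores
  shifted <- m + rnorm(20)
  expect_equal(abs(pca_expr(shifted)$scores), abs(pca_expr(m)$scores),
               tolerance = 1e-9)

  expect_error(pca_expr(m, gene_subset = c("zz1", "zz2")), "fewer than 2")
  sub <- pca_expr(m, gene_subset = paste0("G", 1:5))  # case-insensitive match
  expect_equal(nrow(sub$scores), 10L)
})
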