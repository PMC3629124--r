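# Moderated differential expression: model fit, shrinkage, t statistics,
# BH adjustment, and agreement with the limma reference implementation.

make_groups <- function(nb, ni, nh) {
  factor(rep(c("blastomere", "ICM", "hESC"), c(nb, ni, nh)),
         levels = c("blastomere", "ICM", "hESC"))
}

test_that("fit_groups computes means and pooled variance with df = N - 3", {
  g <- make_groups(2, 2, 2)
  m <- rbind(gene1 = c(1, 1, 2, 2, 3, 3))
  fit <- fit_groups(m, g)
  expect_equal(unname(fit$means[1, ]), c(1, 2, 3))
  expect_equal(unname(fit$s2[1]), 0)
  expect_equal(fit$df, 3L)

  # a single-sample group contributes its mean but no residual df
  g2 <- make_groups(3, 1, 2)
  m2 <- rbind(gene1 = c(1, 2, 3, 9, 4, 6))
  fit2 <- fit_groups(m2, g2)
  expect_equal(fit2$df, 3L)
  expect_equal(unname(fit2$means[1, "ICM"]), 9)
  expect_equal(unname(fit2$s2[1]), (2 + 2) / 3)  # ICM adds nothing to RSS

  expect_error(fit_groups(m[, 1:4, drop = FALSE], factor(c("a", "a", "b", "b"))),
               "3 group")
})

test_that("pooled variance is unbiased for the generating noise", {
  set.seed(10)
  g <- make_groups(10, 3, 5)
  m <- matrix(rnorm(1000 * 18, sd = 0.7), 1000, 18,
              dimnames = list(sprintf("g%04d", 1:1000), NULL))
  fit <- fit_groups(m, g)
  expect_equal(mean(fit$s2), 0.49, tolerance = 0.05)
})

test_that("ebayes_shrink recovers hierarchical parameters", {
  set.seed(20)
  d0 <- 4; s0 <- 0.25; dg <- 45L; n <- 5000L
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  fits <- structure(list(s2 = s2, df = dg), class = "gene_fit")
  par <- ebayes_shrink(fits)
  expect_equal(par$d0, d0, tolerance = 0.20)
  expect_equal(par$s0_sq, s0, tolerance = 0.05)
  # posterior variances lie between observed and prior
  lo <- pmin(s2, par$s0_sq); hi <- pmax(s2, par$s0_sq)
  expect_true(all(par$s2_post >= lo - 1e-12 & par$s2_post <= hi + 1e-12))

  # identical variances: infinite-d0 limit, posterior equals the common value
  fits2 <- structure(list(s2 = rep(0.5, 100), df = 10L), class = "gene_fit")
  par2 <- ebayes_shrink(fits2)
  expect_equal(par2$d0, Inf)
  expect_equal(unname(par2$s2_post), rep(0.5, 100))
})

test_that("ebayes_shrink agrees with limma's squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(21)
  s2 <- (2 * 0.3 / rchisq(2000, 2)) * rchisq(2000, 15) / 15
  fits <- structure(list(s2 = s2, df = 15L), class = "gene_fit")
  ours <- ebayes_shrink(fits)
  ref <- limma::squeezeVar(s2, df = 15)
  expect_equal(ours$d0, ref$df.prior, tolerance = 0.01)
  expect_equal(ours$s0_sq, ref$var.prior, tolerance = 0.01)
  expect_equal(unname(ours$s2_post), ref$var.post, tolerance = 0.01)
})

test_that("moderated t reduces to the pooled two-sample t when d0 = 0", {
  g <- make_groups(3, 2, 3)
  m <- rbind(gene1 = c(1, 2, 3, 2, 2, 3, 4, 5))
  fits <- fit_groups(m, g)
  params <- list(d0 = 0, s0_sq = NA, s2_post = c(gene1 = 1))
  res <- moderated_t(fits, params, "H-B")
  expect_equal(res$t, 2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-2 / sqrt(2 / 3), df = 5), tolerance = 1e-12)

  # equal means give t = 0, p = 1
  m0 <- rbind(gene1 = c(1, 2, 3, 2, 2, 1, 2, 3))
  f0 <- fit_groups(m0, g)
  r0 <- moderated_t(f0, list(d0 = 0, s2_post = c(gene1 = 1)), "H-B")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # zero posterior variance: infinite t, p = 0, with a warning
  expect_warning(rz <- moderated_t(fits, list(d0 = 0, s2_post = c(gene1 = 0)), "H-B"),
                 "zero posterior")
  expect_equal(rz$p, 0)
})

test_that("moderated t agrees with limma's eBayes on simulated data", {
  skip_if_not_installed("limma")
  cfg <- small_config(rng_seed = 31L)
  sim <- simulate_expression(cfg)
  ct <- contrast_table(sim$exprs, sim$groups)

  design <- stats::model.matrix(~ 0 + sim$groups)
  colnames(design) <- levels(sim$groups)
  fit <- limma::lmFit(sim$exprs, design)
  cm <- limma::makeContrasts(hESC - blastomere, levels = design)
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  expect_equal(attr(ct, "d0"), fit2$df.prior, tolerance = 0.01)
  expect_equal(attr(ct, "s0_sq"), fit2$s2.prior, tolerance = 0.01)
  expect_equal(unname(ct$t_H.B), unname(fit2$t[, 1]), tolerance = 1e-6)
  expect_equal(unname(ct$p_H.B), unname(fit2$p.value[, 1]), tolerance = 1e-6)
})

test_that("null p-values are uniform and type-I error is controlled", {
  cfg <- small_config(effect_size = 0, n_genes = 2000L, n_seed = 80L,
                      rng_seed = 41L)
  sim <- simulate_expression(cfg)
  ct <- contrast_table(sim$exprs, sim$groups)
  ks <- stats::ks.test(ct$p_H.B, "punif")
  expect_gt(ks$p.value, 0.01)
  # BH-adjusted discoveries in any contrast stay within the nominal rate
  any_sig <- ct$sig_H.B | ct$sig_H.I | ct$sig_I.B
  se <- sqrt(0.05 * 0.95 / nrow(ct))
  expect_lte(mean(any_sig), 0.05 + 3 * se)
})

test_that("bh_adjust matches the step-up oracle and preserves ordering", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(50)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in p
  }
})
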