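# Hypergeometric term enrichment, slim rollup, comparison battery.

test_that("fisher_term_test matches direct enumeration on the 2-of-4 case", {
  # background {A,B,C,D}, term on {A,B}; query {A,B}: of the C(4,2) = 6
  # equally likely 2-gene draws only one contains both annotated genes
  ann <- data.frame(gene = c("A", "B"), term = "T1")
  r <- fisher_term_test(c("A", "B"), c("A", "B", "C", "D"), ann, "T1")
  draws <- combn(c("A", "B", "C", "D"), 2)
  k_draw <- colSums(matrix(draws %in% c("A", "B"), nrow = 2))
  expect_equal(r$p, mean(k_draw >= 2))
  expect_equal(r$p, 1 / 6)
  expect_equal(attr(r, "members"), c("A", "B"))

  # a term annotating every background gene is never over-represented
  ann_all <- data.frame(gene = c("A", "B", "C", "D"), term = "T1")
  expect_equal(fisher_term_test(c("A", "B"), c("A", "B", "C", "D"),
                                ann_all, "T1")$p, 1)
  # k = 0 gives p = 1 for over-representation
  expect_equal(fisher_term_test(c("C", "D"), c("A", "B", "C", "D"),
                                ann, "T1")$p, 1)
  expect_error(fisher_term_test(c("A", "Z"), c("A", "B"), ann, "T1"), "subset")
})

test_that("tail sums equal the binomial-coefficient oracle over small tables", {
  # every (N, K, n, k) with N <= 12: compare phyper tail against the direct
  # sum of C(K,j) C(N-K,n-j) / C(N,n); the full N <= 30 sweep runs in the
  # acceptance suite
  for (N in 2:12) {
    for (K in 1:N) {
      for (n in 1:N) {
        j <- max(0, n + K - N):min(n, K)
        pmass <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
        for (k in j) {
          expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       sum(pmass[j >= k]), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("one-sided p agrees with fisher.test", {
  set.seed(60)
  for (i in 1:20) {
    N <- sample(10:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    bg <- sprintf("g%02d", 1:N)
    ann <- data.frame(gene = bg[1:K], term = "T")
    q <- sample(bg, n)
    r <- fisher_term_test(q, bg, ann, "T")
    tab <- matrix(c(r$k, r$K - r$k, r$n - r$k, r$N - r$K - r$n + r$k), 2)
    expect_equal(r$p, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("slim rollup equals the naive per-pair ancestor walk", {
  slim <- list(terms = data.frame(term = c("S1", "S2")),
               ancestors = data.frame(term = c("c1", "c2", "c3", "m1"),
                                      ancestor = c("m1", "S2", "ORPHAN", "S1")))
  ann <- data.frame(gene = c("gA", "gA", "gB", "gC", "gD"),
                    term = c("c1", "c2", "c1", "S1", "c3"))
  rolled <- slim_rollup(ann, slim)
  # independent brute force: walk each pair's ancestors recursively
  walk <- function(tm) {
    up <- slim$ancestors$ancestor[slim$ancestors$term == tm]
    unique(c(tm, unlist(lapply(up, walk))))
  }
  expected <- unique(do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    anc <- intersect(walk(ann$term[i]), slim$terms$term)
    if (length(anc)) data.frame(gene = ann$gene[i], term = anc) else NULL
  })))
  expect_setequal(paste(rolled$gene, rolled$term),
                  paste(expected$gene, expected$term))
  # multi-hop: gA's c1 reaches S1 via m1; direct slim annotation unchanged
  expect_true(any(rolled$gene == "gA" & rolled$term == "S1"))
  expect_true(any(rolled$gene == "gC" & rolled$term == "S1"))
  # terms with no slim ancestor are reported unmapped
  expect_true("c3" %in% attr(rolled, "unmapped"))
  expect_error(slim_rollup(ann, list(terms = data.frame(term = character(0)))),
               "empty")
})

test_that("the comparison battery recovers a planted enriched term", {
  cfg <- small_config(rng_seed = 19L)
  run <- run_simulation_study(cfg)
  ivtps <- run$enrichment$records
  vs_genome <- ivtps[ivtps$comparison == "IVTPS_vs_genome", ]
  slim_parent <- "SLIM:0001"  # the planted child term's ancestor
  expect_equal(vs_genome$term[which.min(vs_genome$padj)], slim_parent)
  # the significance flag is consistent with padj, alpha and direction
  expect_equal(ivtps$significant,
               ivtps$padj < ivtps$alpha & ivtps$direction == "over")
  # percentage table has one column per non-empty signature, values in [0,100]
  pct <- run$enrichment$percent_table
  expect_true(all(pct >= 0 & pct <= 100))
  expect_equal(nrow(pct), 33L)
})

test_that("a query tested against itself finds nothing", {
  cfg <- small_config(rng_seed = 23L)
  sim <- simulate_expression(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  q <- sim$truth$gene[1:50]
  r <- enrich_terms(q, q, ann$annotations)
  expect_true(all(r$p == 1))
})

test_that("null enrichment p-values are exactly uniform after de-discretization", {
  # p_in = p_out: the planted term carries no signal. The exact test's
  # discrete p-value P(X >= k) becomes Uniform(0,1) under the randomized
  # transform p - U * P(X = k), which is what a calibrated exact tail implies.
  cfg <- small_config(p_in = 0.1, p_out = 0.1, rng_seed = 29L)
  sim <- simulate_expression(cfg)
  query <- sim$truth$gene[sim$truth$true_signature == "IVTPS"]
  bg <- sim$truth$gene
  set.seed(29)
  p_rand <- replicate(200, {
    hit <- runif(length(bg)) < 0.1
    ann <- data.frame(gene = bg[hit], term = "T")
    if (!any(hit)) return(runif(1))
    r <- fisher_term_test(query, bg, ann, "T")
    point <- stats::dhyper(r$k, r$K, r$N - r$K, r$n)
    r$p - runif(1) * point
  })
  expect_gt(stats::ks.test(p_rand, "punif")$p.value, 0.01)
  # and the reported (conservative) p-values respect the nominal level
  expect_lte(mean(p_rand <= 0.05) , 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
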