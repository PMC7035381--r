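test_that("moments use the population (1/N) convention", {
  expect_equal(moments(c(0, 0, 10, 10)), c(mu = 5, sigma2 = 25))
  expect_equal(moments(c(2, 4, 6)), c(mu = 4, sigma2 = 8 / 3))
  expect_equal(moments(c(0, 0, 0)), c(mu = 0, sigma2 = 0))
  expect_equal(moments(c(2, 4, 6), var_method = "sample")[["sigma2"]], 4)
  expect_error(moments(integer(0)), "empty")
})

test_that("p and alpha estimators match the two-point model identities", {
  # one 10 among ten cells: mu = 1, sigma2 = 9 -> p = 1/9, alpha = 9,
  # the two-point values p/(1-p) and alpha(1-p) for true p = 0.1, alpha = 10
  m <- moments(c(10, rep(0, 9)))
  expect_equal(estimate_p(m[["mu"]], m[["sigma2"]]), 1 / 9)
  expect_equal(estimate_alpha(m[["mu"]], m[["sigma2"]]), 9)
  expect_equal(estimate_alpha(5, 25), 5)
  expect_equal(estimate_alpha(3, 3), 1)            # Poisson boundary -> A = 0
  # degenerate branches
  expect_equal(estimate_p(0, 0), 0)
  expect_equal(estimate_p(4, 0), 1)                # constant gene
  expect_equal(estimate_p(10, 1), 1)               # clipped sub-Poissonian
  expect_true(all(is_degenerate(c(0, 4, 10), c(0, 0, 1))))
  expect_false(is_degenerate(1, 9))
  expect_error(estimate_p(-1, 2), "non-negative")
  expect_error(estimate_alpha(0, 2), "mu = 0")
})

test_that("logarithmic variables and the intermittency call behave as defined", {
  la <- to_log(0.2, exp(3))
  expect_equal(la$I, log(5))
  expect_equal(la$A, 3)
  expect_equal(to_log(1, 1), data.frame(I = 0, A = 0))
  expect_error(to_log(0, 1), "p must")
  expect_error(to_log(0.5, -2), "alpha must")
  expect_true(classify_intermittent(1.7))
  expect_false(classify_intermittent(log(5)))      # strict inequality
  expect_false(classify_intermittent(0))
})

test_that("p * alpha = mu exactly on non-degenerate entries; permutation invariant", {
  set.seed(11)
  for (rep in 1:20) {
    counts <- rpois(50, runif(1, 0.5, 8)) * rbinom(50, 1, runif(1, 0.2, 0.9))
    m <- moments(counts)
    if (m[["mu"]] == 0 || is_degenerate(m[["mu"]], m[["sigma2"]])) next
    p <- estimate_p(m[["mu"]], m[["sigma2"]])
    a <- estimate_alpha(m[["mu"]], m[["sigma2"]])
    expect_equal(p * a, m[["mu"]], tolerance = 1e-12)
    mp <- moments(sample(counts))
    expect_identical(mp[["mu"]], m[["mu"]])
    expect_equal(mp[["sigma2"]], m[["sigma2"]], tolerance = 1e-12)
  }
})

test_that("gene_tissue_stats excludes absent genes and flags degeneracy", {
  m <- rbind(c(4, 0, 3, 7), c(6, 0, 3, 7), c(0, 0, 3, 0), c(0, 0, 3, 7))
  cm <- toy_cm(m, tissue = c("a", "a", "b", "b"))
  st <- gene_tissue_stats(cm)
  # gene g2 is all-zero everywhere, g1 absent from tissue b
  expect_false("g2" %in% st$gene_id)
  expect_equal(nrow(st[st$gene_id == "g1", ]), 1L)
  g1a <- st[st$gene_id == "g1" & st$tissue == "a", ]
  expect_equal(g1a$mu, 5); expect_equal(g1a$sigma2, 1)
  expect_equal(g1a$p, 1); expect_true(g1a$degenerate)  # mu^2 > sigma2, clipped
  g3 <- st[st$gene_id == "g3", ]
  expect_true(all(g3$degenerate))                      # constant gene
  expect_true(all(g3$I == 0))
  # spike-ins excluded by default, included on request
  cm_sp <- toy_cm(m, tissue = c("a", "a", "b", "b"),
                  spikein = c(FALSE, FALSE, FALSE, TRUE))
  expect_false("g4" %in% gene_tissue_stats(cm_sp)$gene_id)
  expect_true("g4" %in% gene_tissue_stats(cm_sp, include_spikeins = TRUE)$gene_id)
})

test_that("tissue summaries center the per-tissue deviations", {
  st <- data.frame(gene_id = rep(c("x", "y"), c(3, 1)),
                   tissue = c("a", "b", "c", "a"),
                   A = c(1, 2, 3, 5), I = c(0, 0, 0, 2),
                   degenerate = FALSE)
  gs <- tissue_summary(st)
  expect_equal(gs$summary$A_bar, c(2, 5))
  expect_equal(gs$deltas$dA[gs$deltas$gene_id == "x"], c(-1, 0, 1))
  expect_equal(gs$deltas$dA[gs$deltas$gene_id == "y"], 0)   # single tissue
  agg <- tapply(gs$deltas$dA, gs$deltas$gene_id, sum)
  expect_true(all(abs(agg) < 1e-12))
  expect_error(tissue_summary(st[0, ]), "no usable")
})

test_that("dispersion variances pool deviations and build the 20x20 lattice", {
  st <- data.frame(gene_id = "x", tissue = c("a", "b", "c"),
                   A = c(1, 2, 3), I = c(0, 0, 0), degenerate = FALSE)
  d <- dispersion_variances(tissue_summary(st))
  expect_equal(d$var_dA, 2 / 3)      # population variance of (-1, 0, 1)
  expect_equal(d$var_dI, 0)
  expect_equal(dim(d$heatmap$counts), c(20L, 20L))
  expect_equal(sum(d$heatmap$counts), 3L)
  st2 <- data.frame(gene_id = rep(c("x", "y"), each = 2),
                    tissue = c("a", "b"), A = 2, I = 1, degenerate = FALSE)
  d2 <- dispersion_variances(tissue_summary(st2))
  expect_equal(c(d2$var_dA, d2$var_dI), c(0, 0))
})
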