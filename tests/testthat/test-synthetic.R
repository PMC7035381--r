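test_that("always-on fixed-mode gene gives constant counts and I = 0", {
  g <- intermittent_genes("g1", p = 1, alpha = 50)
  cm <- gen_intermittent_counts(g, c(t1 = 200), mode = "fixed", seed = 5)
  v <- as.numeric(cm$counts[, 1])
  expect_true(all(v == 50))
  st <- gene_tissue_stats(cm)
  expect_equal(st$I, 0)
  expect_true(st$degenerate)
})

test_that("intermittent generator moments follow the Bernoulli-mixture oracle", {
  # fixed-count mode: mu = alpha*p, sigma2 = p(1-p)alpha^2, so the
  # estimators converge to p/(1-p) and alpha(1-p)
  g <- intermittent_genes("g1", p = 0.1, alpha = 100)
  cm <- gen_intermittent_counts(g, c(t1 = 5e4), mode = "fixed", seed = 42)
  v <- as.numeric(cm$counts[, 1])
  expect_true(all(v %in% c(0, 100)))
  expect_equal(mean(v > 0), 0.1, tolerance = 0.05)   # binomial concentration
  st <- gene_tissue_stats(cm)
  p_se <- batch_se(v, function(b) {
    m <- moments(b); estimate_p(m[["mu"]], m[["sigma2"]])
  })
  a_se <- batch_se(v, function(b) {
    m <- moments(b); estimate_alpha(m[["mu"]], m[["sigma2"]])
  })
  expect_lt(abs(st$p - 0.1 / 0.9), 3 * p_se)
  expect_lt(abs(st$alpha - 90), 3 * a_se)
})

test_that("tissue overrides and ground truth are honoured", {
  g <- intermittent_genes(c("g1", "g2"), p = 0.5, alpha = 30)
  ov <- data.frame(gene_id = "g1", tissue = "t2", p = 0.05)
  cm <- gen_intermittent_counts(g, c(t1 = 400, t2 = 400), p_overrides = ov,
                                seed = 9)
  gt <- attr(cm, "ground_truth")
  expect_equal(nrow(gt), 4L)
  expect_equal(gt$p_true[gt$gene_id == "g1" & gt$tissue == "t2"], 0.05)
  on_frac <- mean(cm$counts[cm$cells$tissue == "t2", 1] > 0)
  expect_lt(on_frac, 0.2)
  expect_error(gen_intermittent_counts(g[0, ], c(t1 = 10)), "empty")
  expect_error(gen_intermittent_counts(g, c(t1 = 0)), "positive")
})

test_that("genes sharing a program are co-activated", {
  g <- intermittent_genes(c("g1", "g2"), p = 0.3, alpha = 40,
                          program = "prog1")
  cm <- gen_intermittent_counts(g, c(t1 = 3000), mode = "fixed", seed = 21)
  pc <- pair_correlation(as.numeric(cm$counts[, 1]),
                         as.numeric(cm$counts[, 2]))
  expect_equal(pc$C, 1)     # identical activation draws, fixed counts
})

test_that("differentiated counts are exclusive across types, K = -1 exactly", {
  spec <- differentiation_spec(c(t1 = 0.5, t2 = 0.5),
                               c(g1 = "t1", g2 = "t2"), level = c(20, 30))
  cm <- gen_differentiated_counts(spec, 1000, seed = 3)
  gt <- attr(cm, "ground_truth")
  v1 <- as.numeric(cm$counts[, 1]); v2 <- as.numeric(cm$counts[, 2])
  expect_equal(sum(v1 * v2), 0)               # never co-expressed
  expect_true(all(v1[gt$cell_type == "t2"] == 0))
  pc <- pair_correlation(v1, v2)
  expect_identical(pc$K, -1)
  # single type at frequency 1 reduces to always-on expression
  solo <- differentiation_spec(c(only = 1), c(g1 = "only"), 10)
  cm1 <- gen_differentiated_counts(solo, 100, mode = "fixed", seed = 1)
  expect_true(all(as.numeric(cm1$counts[, 1]) == 10))
  bad <- spec; bad$type_freq <- c(t1 = 0.6, t2 = 0.6)
  expect_error(differentiation_spec(bad$type_freq, bad$gene_type, 1),
               "sum to 1")
})

test_that("telegraph sampler reproduces the closed-form stationary moments", {
  tp <- telegraph_params(0.01, 0.09, 100, 1)
  cm <- gen_telegraph_counts(tp, 1e5, seed = 17)
  v <- as.numeric(cm$counts[, 1])
  th <- stationary_moments(tp)
  expect_lt(abs(mean(v) - th[["mean"]]), 3 * se_mean(v))
  pvar <- mean(v^2) - mean(v)^2
  expect_lt(abs(pvar - th[["variance"]]), 3 * se_var(v))
  # degenerate corners
  cm0 <- gen_telegraph_counts(telegraph_params(1, 1, 0, 1), 100, seed = 1)
  expect_true(all(as.numeric(cm0$counts[, 1]) == 0))
  cmP <- gen_telegraph_counts(telegraph_params(1, 0, 50, 1), 2e4, seed = 2)
  vP <- as.numeric(cmP$counts[, 1])
  expect_equal(var(vP) / mean(vP), 1, tolerance = 0.05)   # Poisson limit
  expect_error(telegraph_params(-1, 1, 10, 1), "non-negative")
})

test_that("spike-in generator is deterministic without noise and linear in concentration", {
  panel <- spikein_panel(c("ERCC-00001", "ERCC-00002"),
                         concentration = c(50, 100))
  cm <- gen_spikein_counts(panel, 50, seed = 4)
  m <- as.matrix(cm$counts)
  expect_true(all(m[, 1] == 50) && all(m[, 2] == 100))   # identical per cell
  expect_equal(m[1, 2] / m[1, 1], 2)                     # linearity
  expect_true(all(cm$genes$is_spikein))
  st <- gene_tissue_stats(cm, include_spikeins = TRUE)
  expect_equal(st$I, c(0, 0))                            # zero intermittency
  expect_error(gen_spikein_counts(panel[0, ], 10), "empty")
  expect_error(gen_spikein_counts(panel, 10, cell_scale_variation = -1),
               "non-negative")
})
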