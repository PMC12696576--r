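test_that("same seed and config give a byte-identical cohort", {
  a <- simulate_cohort(cohort_config(seed = 8))
  b <- simulate_cohort(cohort_config(seed = 8))
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cohort_config(seed = 9))
  expect_false(identical(as.data.frame(a$cohort), as.data.frame(c$cohort)))
})

test_that("zero loading gives independent items, loading one comonotone items", {
  zero <- stats::setNames(rep(0, 6), c("MDD", "GAD", "OCD", "PD", "SAD", "SP"))
  sim0 <- simulate_cohort(complete_config(10000, seed = 5,
                                          subscale_loading = zero))
  X <- as.matrix(as.data.frame(sim0$cohort)[, sprintf("item_%02d", 1:47)])
  R <- cor(X[, 1:12], method = "spearman")
  expect_lt(mean(abs(R[upper.tri(R)])), 0.05)

  # identical cutpoints + loading 1: items inside a subscale are identical
  # transforms of the severity, so pairwise Spearman is exactly 1
  one <- stats::setNames(rep(1, 6), c("MDD", "GAD", "OCD", "PD", "SAD", "SP"))
  cuts <- matrix(rep(c(0.2, 1.0, 1.8), each = 47), 47, 3)
  sim1 <- simulate_cohort(complete_config(400, seed = 6,
                                          subscale_loading = one,
                                          threshold_sets = cuts))
  bank <- rcads_item_bank()
  ids <- bank$items$item_id[bank$items$subscale == "GAD"]
  Xg <- as.matrix(as.data.frame(sim1$cohort)[, sprintf("item_%02d", ids)])
  Rg <- cor(Xg, method = "spearman")
  expect_equal(unname(Rg[upper.tri(Rg)]), rep(1, sum(upper.tri(Rg))))
})

test_that("class counts follow the configured multinomial mix", {
  counts <- matrix(0, 500, 3)
  for (s in seq_len(500)) {
    sim <- simulate_cohort(complete_config(89, seed = 10000 + s))
    counts[s, ] <- tabulate(sim$truth$classes + 1L, 3L)
  }
  expect_equal(colSums(counts) / 500, c(49, 6, 34), tolerance = 1 / 49)
  expect_true(all(abs(colMeans(counts) - c(48.95, 6.23, 33.82)) < 1))
})

test_that("marginal frequencies match the exact ground-truth probabilities", {
  sim <- simulate_cohort(complete_config(10000, seed = 77))
  X <- as.matrix(as.data.frame(sim$cohort)[, sprintf("item_%02d", 1:47)])
  n <- nrow(X)
  for (i in c(1, 5, 23, 47)) {
    emp <- tabulate(X[, i] + 1L, 4L) / n
    p <- sim$truth$item_probs[i, ]
    expect_true(all(abs(emp - p) <= 3 * sqrt(p * (1 - p) / n) + 1e-12))
  }
})

test_that("within-subscale correlation increases with the loading", {
  mean_r <- vapply(c(0, 0.4, 0.8), function(a) {
    load <- stats::setNames(rep(a, 6), c("MDD", "GAD", "OCD", "PD", "SAD", "SP"))
    sim <- simulate_cohort(complete_config(5000, seed = 3,
                                           subscale_loading = load))
    bank <- rcads_item_bank()
    ids <- bank$items$item_id[bank$items$subscale == "MDD"]
    X <- as.matrix(as.data.frame(sim$cohort)[, sprintf("item_%02d", ids)])
    R <- cor(X, method = "spearman")
    mean(R[upper.tri(R)])
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0.05))
  # ground-truth correlations should track the same ordering
  tr <- vapply(c(0, 0.4, 0.8), function(a) {
    load <- stats::setNames(rep(a, 6), c("MDD", "GAD", "OCD", "PD", "SAD", "SP"))
    sim_cfg <- complete_config(10, seed = 1, subscale_loading = load)
    rcadscreen:::true_subscale_spearman(sim_cfg)[["MDD"]]
  }, numeric(1))
  expect_true(all(diff(tr) > 0))
  expect_equal(mean_r, tr, tolerance = 0.05)
})

test_that("norm tables are deterministic, positive-sd and self-standardising", {
  cfg <- complete_config(10, seed = 19, class_mix = c(1, 0, 0))
  n1 <- build_norms(cfg, reference_n = 1500, seed = 4)
  n2 <- build_norms(cfg, reference_n = 1500, seed = 4)
  expect_identical(n1, n2)
  expect_true(all(n1$entries$sd > 0))
  expect_error(build_norms(cfg, reference_n = 500), "pooled")

  # scoring a fresh Normal-regime sample against its own norms recovers the
  # T-scale: mean about 50, sd about 10
  norms <- build_norms(cfg, reference_n = 5000, seed = 4)
  sim <- simulate_cohort(complete_config(5000, seed = 23, class_mix = c(1, 0, 0)))
  sc <- score_cohort(sim$cohort, norms = norms)
  expect_equal(mean(sc$t_score), 50, tolerance = 0.5 / 50)
  expect_equal(sd(sc$t_score), 10, tolerance = 0.5 / 10)
})

test_that("missingness counts exceeding the cohort size are rejected", {
  expect_error(cohort_config(n = 20, missing_sex = 12, missing_grade = 10,
                             missing_both = 1), "exceed")
  expect_error(cohort_config(missing_both = 20), "missing_both")
})
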