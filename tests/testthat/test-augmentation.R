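test_that("fitted marginals are the empirical frequencies", {
  set.seed(2)
  X <- matrix(sample(0:3, 100 * 47, replace = TRUE), 100, 47)
  X[, 1] <- rep(0:3, times = c(10, 20, 30, 40))
  fit <- fit_augmentation(manual_cohort(X), calibrate = FALSE)
  expect_equal(unname(fit$item_probs[1, ]), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(rowSums(fit$item_probs)), rep(1, 47), tolerance = 1e-12)
  expect_equal(fit$fitted_n, 100)

  expect_warning(fit1 <- fit_augmentation(manual_cohort(X[1, , drop = FALSE]),
                                          calibrate = FALSE), "single-record")
  expect_true(all(fit1$item_probs %in% c(0, 1)))
  expect_error(fit_augmentation(manual_cohort(X[0, , drop = FALSE])), "empty")
})

test_that("goodness of fit against reference probabilities is calibrated", {
  p <- gof_multinomial(c(10, 20, 30, 40), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(as.numeric(p), 1)
  expect_equal(attr(p, "statistic"), 0)
  expect_equal(as.numeric(gof_multinomial(c(25, 25, 25, 25), rep(0.25, 4))), 1)
  expect_error(gof_multinomial(c(1, 0, 0, 1), c(0.5, 0.5, 0, 0)),
               "zero-probability")

  # draws from the reference reject at about the nominal rate
  set.seed(31)
  ref <- c(0.4, 0.3, 0.2, 0.1)
  rej <- mean(vapply(1:1000, function(r) {
    counts <- as.vector(rmultinom(1, 89, ref))
    as.numeric(gof_multinomial(counts, ref)) < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("latent correlation calibration is monotone and handles the edges", {
  probs <- list(c(0.4, 0.3, 0.2, 0.1), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(calibrate_latent_rho(0, probs), 0)
  expect_warning(hi <- calibrate_latent_rho(0.999, probs), "clamp")
  expect_gte(hi, 0.99)

  grid_vals <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), induced_spearman,
                      numeric(1), probs_list = probs)
  expect_true(all(diff(grid_vals) > 0))
  expect_equal(grid_vals[1], 0)
  # discretisation attenuates: induced is below the latent value
  expect_true(all(grid_vals[-1] < c(0.2, 0.4, 0.6, 0.8)))
})

test_that("copula sampling preserves marginals and independence limits", {
  set.seed(9)
  X <- matrix(sample(0:3, 89 * 47, replace = TRUE, prob = c(.4, .3, .2, .1)),
              89, 47)
  fit <- fit_augmentation(manual_cohort(X), calibrate = FALSE)

  # zero latent correlation: empirical pairwise correlations vanish
  fit0 <- fit
  fit0$latent_rho[] <- 0
  S <- sample_items(fit0, "MDD", 10000, seed = 4)
  R <- cor(S)
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)

  # marginal preservation at large n
  S2 <- sample_items(fit, "GAD", 100000, seed = 5)
  for (j in 1:2) {
    emp <- tabulate(S2[, j] + 1L, 4L) / nrow(S2)
    pr <- fit$item_probs[colnames(S2)[j], ]
    expect_true(all(abs(emp - pr) <= 3 * sqrt(pr * (1 - pr) / nrow(S2)) + 1e-12))
  }

  # degenerate marginal: constant column
  fit$item_probs["item_01", ] <- c(1, 0, 0, 0)
  S3 <- sample_items(fit, "GAD", 500, seed = 6)
  expect_equal(unname(S3[, "item_01"]), rep(0L, 500))
})

test_that("synthetic cohorts have ratio x fitted_n records, deterministically", {
  sim <- simulate_cohort(complete_config(89, seed = 31))
  fit <- fit_augmentation(sim$cohort)
  norms <- shared_norms()
  s4 <- generate_synthetic(fit, ratio = 4, seed = 2, norms = norms)
  expect_equal(nrow(s4), 356)
  expect_identical(attr(s4, "provenance"), "synthetic")
  expect_true(all(c("raw_total", "t_score", "label") %in% names(s4)))

  s4b <- generate_synthetic(fit, ratio = 4, seed = 2, norms = norms)
  expect_identical(as.data.frame(s4), as.data.frame(s4b))

  s20 <- generate_synthetic(fit, ratio = 20, seed = 3, norms = norms)
  expect_equal(nrow(s20), 1780)

  expect_warning(generate_synthetic(fit, ratio = 3, seed = 2, norms = norms),
                 "ratio")
  expect_error(generate_synthetic(fit, ratio = 4, seed = 2, norms = NULL),
               "norm")

  # simulate() S3 method is a thin wrapper
  s4c <- simulate(fit, seed = 2, ratio = 4, norms = norms)
  expect_identical(as.data.frame(s4c), as.data.frame(s4))
})

test_that("hybrid assembly is order-stable concatenation with bookkeeping", {
  sim <- simulate_cohort(complete_config(89, seed = 32))
  norms <- shared_norms()
  scored <- score_cohort(sim$cohort, norms = norms)
  scored_co <- rcadscreen:::new_cohort(scored, "real")
  fit <- fit_augmentation(sim$cohort)
  synth <- generate_synthetic(fit, ratio = 4, seed = 5, norms = norms)

  hy <- make_hybrid(scored_co, synth)
  expect_equal(nrow(hy), 445)
  expect_identical(attr(hy, "provenance"), "hybrid")
  expect_equal(attr(hy, "ratio"), 4L)
  expect_equal(as.data.frame(hy)[1:89, ], as.data.frame(scored_co),
               ignore_attr = TRUE)

  # class counts add up
  counts <- function(d) vapply(0:2, function(k) sum(d$label == k), integer(1))
  expect_equal(counts(as.data.frame(hy)),
               counts(scored) + counts(as.data.frame(synth)))

  empty <- synth[0, ]
  hy0 <- make_hybrid(scored_co, rcadscreen:::new_cohort(empty, "synthetic"))
  expect_equal(nrow(hy0), 89)
  expect_identical(attr(hy0, "provenance"), "hybrid")

  expect_error(make_hybrid(sim$cohort, synth), "schema")
})

test_that("fidelity of an exact copy is perfect", {
  sim <- simulate_cohort(complete_config(60, seed = 33))
  fid <- fidelity(sim$cohort, sim$cohort)
  expect_equal(unname(fid$marginal_tv), rep(0, 47))
  expect_equal(unname(fid$mw_p), rep(1, 47), tolerance = 1e-12)
  expect_true(all(fid$corr_gap < 1e-12))
})
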