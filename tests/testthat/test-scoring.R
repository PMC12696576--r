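test_that("T-score thresholds partition the line at 65 and 70", {
  expect_equal(classify_tscore(c(64.9, 65.0, 69.9, 70.0)), c(0L, 1L, 1L, 2L))
  # exhaustive partition: every real t gets exactly one label
  t <- seq(-50, 150, by = 0.1)
  lab <- classify_tscore(t)
  expect_true(all(lab %in% 0:2))
  expect_equal(lab[t < 65], rep(0L, sum(t < 65)))
  expect_equal(lab[t >= 70], rep(2L, sum(t >= 70)))
})

test_that("scoring follows the affine T-score form", {
  norms <- flat_norms(mean = 40, sd = 14)
  X <- matrix(0L, 3, 47)
  co <- manual_cohort(X)
  sc <- score_cohort(co, norms = norms)
  expect_equal(sc$raw_total, rep(0L, 3))
  expect_equal(sc$t_score, rep(50 - 10 * 40 / 14, 3))

  # a record at the norm-group mean raw score scores exactly T = 50
  X2 <- matrix(0L, 1, 47); X2[1, 1:20] <- 2L  # raw 40
  sc2 <- score_cohort(manual_cohort(X2), norms = norms)
  expect_equal(sc2$raw_total, 40L)
  expect_equal(sc2$t_score, 50)

  # subscale sums add to the total
  sim <- simulate_cohort(complete_config(15, seed = 9))
  sc3 <- score_cohort(sim$cohort, norms = norms)
  sub_cols <- paste0("raw_", tolower(c("MDD", "GAD", "OCD", "PD", "SAD", "SP")))
  expect_equal(rowSums(sc3[, sub_cols]), as.numeric(sc3$raw_total),
               ignore_attr = TRUE)
})

test_that("scoring is monotone in every response", {
  norms <- flat_norms()
  set.seed(31)
  X <- matrix(sample(0:2, 47 * 4, replace = TRUE), 4, 47)
  base <- score_cohort(manual_cohort(X), norms = norms)
  for (i in 1:4) {
    for (j in sample(1:47, 5)) {
      X2 <- X
      X2[i, j] <- X2[i, j] + 1L
      bumped <- score_cohort(manual_cohort(X2), norms = norms)
      expect_gt(bumped$raw_total[i], base$raw_total[i])
      expect_gt(bumped$t_score[i], base$t_score[i])
    }
  }
})

test_that("norm tables are validated", {
  grid <- expand.grid(grade = 2:12, sex = c("boy", "girl"),
                      stringsAsFactors = FALSE)
  expect_error(norm_table(cbind(grid, mean = 40, sd = 0)), "sd")
  expect_error(norm_table(cbind(grid[-1, ], mean = 40, sd = 10)), "misses")
  expect_error(norm_table(cbind(grid[c(1, 1:22), ], mean = 40, sd = 10)),
               "duplicate")
  # missing cell at lookup time
  norms <- flat_norms()
  sim <- simulate_cohort(complete_config(3, seed = 2))
  co <- as.data.frame(sim$cohort)
  co$grade <- 12L
  norms$entries <- norms$entries[!(norms$entries$grade == 12 &
                                     norms$entries$sex == "boy"), ]
  expect_error(score_cohort(manual_cohort(as.matrix(co[, -(1:2)]),
                                          sex = "boy", grade = 12L),
                            norms = norms), "no norm entry")
})

test_that("retained-vs-dropped comparison behaves like a two-sample t-test", {
  sim <- simulate_cohort(cohort_config(seed = 13))
  flt <- filter_complete(sim$cohort)
  # identical groups: t exactly 0
  res0 <- compare_retained_dropped(flt$retained, flt$retained)
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)

  # separated groups: decisive rejection
  hi <- as.data.frame(flt$retained)
  hi[, sprintf("item_%02d", 1:47)] <- 3L
  res1 <- compare_retained_dropped(
    flt$retained, rcadscreen:::new_cohort(hi, "real"))
  expect_lt(res1$p_value, 1e-10)

  # dropped records with missing demographics still contribute raw totals
  expect_equal(compare_retained_dropped(flt$retained, flt$dropped)$n_dropped, 49)
})

test_that("the comparison keeps its nominal size under the null", {
  # split one exchangeable cohort at random into 89 vs 49: H0 holds by
  # construction, so the rejection rate should sit near alpha
  sim <- simulate_cohort(complete_config(138, seed = 41))
  df <- as.data.frame(sim$cohort)
  set.seed(55)
  reps <- 500L
  rejections <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(138, 89)
    res <- compare_retained_dropped(
      rcadscreen:::new_cohort(df[idx, ], "real"),
      rcadscreen:::new_cohort(df[-idx, ], "real"))
    rejections <- rejections + (res$p_value < 0.05)
  }
  expect_gt(rejections / reps, 0.02)
  expect_lt(rejections / reps, 0.08)
})
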