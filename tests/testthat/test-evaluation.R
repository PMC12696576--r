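test_that("SMOTE balances every class to the majority count", {
  set.seed(8)
  X <- matrix(runif(89 * 46), 89, 46)
  y <- rep(0:2, c(49, 6, 34))
  bal <- suppressWarnings(smote_balance(X, y, seed = 2))
  expect_equal(as.vector(table(bal$y)), c(49, 49, 49))
  expect_equal(nrow(bal$X), 147)
  # originals preserved verbatim, first and in order
  expect_equal(bal$X[1:89, ], X, ignore_attr = TRUE)
  expect_equal(bal$y[1:89], y)

  # already balanced: identity
  yb <- rep(0:1, each = 20)
  Xb <- matrix(rnorm(40 * 3), 40, 3)
  bal2 <- smote_balance(Xb, yb, seed = 2)
  expect_equal(bal2$X, Xb, ignore_attr = TRUE)
  expect_equal(bal2$y, yb)

  expect_error(smote_balance(X, rep(0:2, c(88, 1, 0)), seed = 1), "'1'")
})

test_that("SMOTE interpolates between same-class neighbours", {
  # minority class of exactly two points: every synthetic row must lie on
  # the segment between them, coordinate by coordinate
  a <- c(0, 0, 0); b <- c(4, 2, 8)
  X <- rbind(matrix(rnorm(30, mean = 50), 10, 3), a, b)
  y <- c(rep(0, 10), 1, 1)
  expect_warning(bal <- smote_balance(X, y, k = 5, seed = 3), "capped")
  synth <- bal$X[bal$y == 1, ][-(1:2), , drop = FALSE]
  expect_equal(nrow(synth), 8)
  for (j in 1:3) {
    expect_true(all(synth[, j] >= min(a[j], b[j]) - 1e-12))
    expect_true(all(synth[, j] <= max(a[j], b[j]) + 1e-12))
  }
})

test_that("the stratified split has ceiling-rule sizes and partitions indices", {
  set.seed(4)
  X <- matrix(rnorm(147 * 5), 147, 5)
  y <- rep(0:2, each = 49)
  spl <- train_test_split(X, y, seed = 9)
  expect_equal(nrow(spl$X_train), 117)
  expect_equal(nrow(spl$X_test), 30)
  expect_equal(sort(c(spl$idx_train, spl$idx_test)), 1:147)
  expect_equal(as.vector(table(spl$y_test)), c(10, 10, 10))

  spl2 <- train_test_split(matrix(rnorm(20), 10, 2), rep(0:1, 5), seed = 1)
  expect_equal(nrow(spl2$X_train), 8)
  expect_equal(nrow(spl2$X_test), 2)

  expect_error(train_test_split(X, c(rep(0, 146), 1), seed = 1), "fewer than 2")
  expect_error(train_test_split(X[1:4, ], y[1:4], seed = 1), "at least 5")
})

test_that("hyperparameter grids enumerate the documented candidates", {
  expect_equal(nrow(model_grid("RF")), 3 * 4 * 3 * 3)
  expect_equal(nrow(model_grid("SVM")), 4 * 2 * 2)
  expect_equal(nrow(model_grid("LR")), 5 * 2)
  expect_equal(nrow(model_grid("DT")), 4 * 3 * 3 * 2)
  expect_equal(nrow(model_grid("KNN")), 4 * 2 * 2)
  expect_equal(nrow(model_grid("NB")), 0)
})

test_that("grid search returns single-point grids, errors on empty non-NB grids", {
  set.seed(6)
  y <- rep(0:2, each = 12)
  X <- matrix(y + rnorm(36, sd = 0.2), 36, 2) + 0  # separable
  colnames(X) <- c("f1", "f2")

  gs <- grid_search_cv(X, y, "KNN", folds = 3, seed = 1,
                       grid = data.frame(n_neighbors = 3, weights = "distance",
                                         metric = "euclidean"))
  expect_equal(gs$best_params$n_neighbors, 3)
  expect_length(gs$cv_fold_scores, 3)

  expect_error(grid_search_cv(X, y, "RF", grid = data.frame(), folds = 3),
               "empty")
  gs_nb <- grid_search_cv(X, y, "NB", folds = 3, seed = 1)
  expect_equal(gs_nb$best_params, list())

  # perfectly separable training data: tree ensembles reach CV accuracy 1
  for (fam in c("RF", "DT")) {
    gs_sep <- grid_search_cv(X, y, fam, folds = 3, seed = 1,
                             grid = model_grid(fam)[1, , drop = FALSE])
    expect_equal(gs_sep$cv_mean_accuracy, 1)
  }

  expect_error(grid_search_cv(X, rep(c(0, 1, 2), c(17, 17, 2)), "NB", folds = 5),
               "smallest class")
})

test_that("all six families fit, predict and evaluate", {
  set.seed(14)
  y <- rep(0:2, each = 20)
  X <- matrix(rnorm(60 * 4, mean = rep(y, 4)), 60, 4)
  colnames(X) <- paste0("f", 1:4)
  for (fam in c("RF", "SVM", "LR", "DT", "NB", "KNN")) {
    gs <- grid_search_cv(X, y, fam, folds = 3, seed = 2,
                         grid = utils::head(model_grid(fam), 2))
    ev <- evaluate_model(gs$model, X, y)
    expect_s3_class(ev, "rcads_eval")
    expect_gt(ev$accuracy, 0.5)  # strong signal: anything sane clears this
    expect_equal(sum(ev$confusion), 60)
  }
})

test_that("metrics match a hand-worked confusion matrix", {
  cm <- matrix(c(9, 1, 0,
                 0, 7, 0,
                 1, 1, 11), 3, 3, byrow = TRUE,
               dimnames = list(truth = 0:2, predicted = 0:2))
  m <- metrics_from_confusion(cm)
  expect_equal(m$per_class$precision, c(9 / 10, 7 / 9, 11 / 11))
  expect_equal(m$per_class$recall, c(9 / 10, 7 / 7, 11 / 13))
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(m$per_class$f1,
               c(f1(0.9, 0.9), f1(7 / 9, 1), f1(1, 11 / 13)))
  expect_equal(m$accuracy, 27 / 30)
  expect_equal(unname(m$macro_avg["f1"]), mean(m$per_class$f1), tolerance = 1e-12)
  expect_equal(unname(m$weighted_avg["f1"]),
               sum(m$per_class$f1 * c(10, 7, 13)) / 30, tolerance = 1e-12)

  # constant prediction on balanced truth: accuracy and macro recall 1/3
  cm2 <- matrix(c(10, 0, 0, 10, 0, 0, 10, 0, 0), 3, 3, byrow = TRUE)
  expect_warning(m2 <- metrics_from_confusion(cm2), "never predicted")
  expect_equal(m2$accuracy, 1 / 3)
  expect_equal(unname(m2$macro_avg["recall"]), 1 / 3)

  # perfect prediction
  cm3 <- diag(c(5, 5, 5))
  m3 <- metrics_from_confusion(cm3)
  expect_equal(m3$accuracy, 1)
  expect_equal(m3$per_class$f1, rep(1, 3))
})

test_that("evaluation rejects labels outside the three classes", {
  set.seed(1)
  y <- rep(0:2, each = 5)
  X <- matrix(rnorm(15 * 2), 15, 2); colnames(X) <- c("a", "b")
  m <- rcadscreen:::fit_model("DT", X, y, NULL, seed = 1)
  expect_error(evaluate_model(m, X, c(y[-1], 3)), "outside")
})

test_that("paired model comparison matches the closed-form t-test", {
  a <- c(0.92, 0.89, 0.93, 0.90, 0.91)
  expect_equal(compare_models(a, a)$p_value, 1)
  expect_match(compare_models(a, a)$note, "zero")

  expect_error(compare_models(a, a - 0.4), "constant")

  d <- c(0.02, -0.01, 0.03, 0.00, 0.01)
  res <- compare_models(a, a - d)
  # t = mean(d) / (sd(d)/sqrt(5)) = 0.01 / (0.0158114/2.2360680) = sqrt(2)
  expect_equal(res$t_statistic, sqrt(2), tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(sqrt(2), df = 4, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("external validation scores, predicts and survives class imbalance", {
  norms <- shared_norms()
  sim <- simulate_cohort(complete_config(80, seed = 51))
  scored <- score_cohort(sim$cohort, norms = norms)
  X <- as.matrix(scored[, sprintf("item_%02d", 1:47)])
  m <- rcadscreen:::fit_model("RF", X, scored$label, NULL, seed = 3)

  # on the training cohort the report equals the in-sample evaluation
  ev_ext <- external_validate(m, sim$cohort, norms = norms)
  ev_in <- evaluate_model(m, X, scored$label)
  expect_equal(ev_ext$confusion, ev_in$confusion)

  # borderline-heavy external cohort: full matrix reported, no crash
  shifted <- simulate_cohort(complete_config(60, seed = 52,
                                             class_mix = c(0.2, 0.6, 0.2)))
  ev_sh <- suppressWarnings(external_validate(m, shifted$cohort, norms = norms))
  expect_equal(sum(ev_sh$confusion), 60)
  expect_length(ev_sh$per_class$recall, 3)

  expect_error(external_validate(m, sim$cohort[0, ], norms = norms), "empty")
  incomplete <- simulate_cohort(cohort_config(n = 20, missing_sex = 3,
                                              missing_grade = 0, missing_both = 0,
                                              seed = 3))$cohort
  expect_error(external_validate(m, incomplete, norms = norms), "unscorable")
})
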