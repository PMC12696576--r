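# Class balancing, splitting, grid-searched model development and
# multi-class evaluation.

#' SMOTE class balancing
#'
#' Upsamples every minority class to the majority count by interpolation:
#' each synthetic point is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`,
#' `x` a minority point and `x_nn` one of its `k` nearest same-class
#' neighbours (Euclidean). Original rows are preserved verbatim (first, in
#' their input order); synthetic rows follow, grouped by class. Interpolated
#' values are kept continuous by default; `round_levels = TRUE` rounds them
#' back to the ordinal levels.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels.
#' @param k Number of nearest neighbours (default 5); capped at class size
#'   minus one with a warning.
#' @param seed Integer seed.
#' @param round_levels Round interpolated values to whole levels.
#' @return A list with `X` and `y`, every class at the majority count.
#' @export
smote_balance <- function(X, y, k = 5L, seed = 1L, round_levels = FALSE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  set.seed(seed)
  counts <- table(y)
  maj <- max(counts)
  new_X <- list(); new_y <- list()
  for (cl in names(counts)) {
    need <- maj - counts[[cl]]
    if (need == 0L) next
    if (counts[[cl]] < 2L) stop("class '", cl, "' has a single member; SMOTE needs at least 2")
    sub <- X[y == cl, , drop = FALSE]
    k_eff <- min(k, nrow(sub) - 1L)
    if (k_eff < k) warning(sprintf("k capped at %d for class '%s' (class size %d)",
                                   k_eff, cl, nrow(sub)))
    D <- as.matrix(stats::dist(sub))
    diag(D) <- Inf
    ord <- apply(D, 1, function(d) order(d)[seq_len(k_eff)])
    nn <- if (k_eff == 1L) matrix(ord, ncol = 1L) else t(ord)
    base <- sample.int(nrow(sub), need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_eff, need, replace = TRUE))]
    u <- stats::runif(need)
    synth <- sub[base, , drop = FALSE] + u * (sub[pick, , drop = FALSE] - sub[base, , drop = FALSE])
    if (round_levels) synth <- round(synth)
    new_X[[cl]] <- synth
    new_y[[cl]] <- rep(cl, need)
  }
  Xb <- rbind(X, do.call(rbind, new_X))
  yb <- c(as.character(y), unlist(new_y, use.names = FALSE))
  if (is.numeric(y)) yb <- as.numeric(yb)
  if (is.integer(y)) yb <- as.integer(yb)
  rownames(Xb) <- NULL
  list(X = Xb, y = yb)
}

#' Stratified train/test split
#'
#' Deterministic under the seed; test size is `ceiling(n * (1 -
#' train_fraction))`, allocated across classes by largest remainder when
#' stratified.
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param train_fraction Fraction of records in the training set (default
#'   0.8).
#' @param stratified Stratify by label (default).
#' @param seed Integer seed.
#' @return A list with `X_train`, `y_train`, `X_test`, `y_test`,
#'   `idx_train`, `idx_test`.
#' @export
train_test_split <- function(X, y, train_fraction = 0.8, stratified = TRUE,
                             seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y), train_fraction > 0, train_fraction < 1)
  if (n < 5L) stop("need at least 5 records to split")
  test_n <- as.integer(ceiling(n * (1 - train_fraction)))
  set.seed(seed)
  if (stratified) {
    counts <- table(y)
    if (any(counts < 2L)) {
      stop("stratified split impossible: class(es) with fewer than 2 members: ",
           paste(names(counts)[counts < 2L], collapse = ", "))
    }
    quota <- as.numeric(counts) * test_n / n
    take <- floor(quota)
    short <- test_n - sum(take)
    if (short > 0) {
      bump <- order(quota - take, decreasing = TRUE)[seq_len(short)]
      take[bump] <- take[bump] + 1
    }
    idx_test <- unlist(lapply(seq_along(counts), function(i) {
      pool <- which(y == names(counts)[i])
      sample(pool, min(take[i], length(pool)))
    }), use.names = FALSE)
  } else {
    idx_test <- sample.int(n, test_n)
  }
  idx_test <- sort(idx_test)
  idx_train <- setdiff(seq_len(n), idx_test)
  list(X_train = X[idx_train, , drop = FALSE], y_train = y[idx_train],
       X_test = X[idx_test, , drop = FALSE], y_test = y[idx_test],
       idx_train = idx_train, idx_test = idx_test)
}

#' Hyperparameter grids for the six classifier families
#'
#' Returns the candidate grid searched for each family: RF (number of trees
#' 50/100/200, maximum depth unlimited/10/20/30, minimum samples to split
#' 2/5/10, minimum samples per leaf 1/2/4), SVM (C 0.1/1/10/100, kernel
#' linear/rbf, gamma scale/auto), LR (C 0.01/0.1/1/10/100, penalty l1/l2),
#' DT (depth/split/leaf as RF, criterion gini/entropy), KNN (neighbours
#' 3/5/7/9, weights uniform/distance, metric euclidean/manhattan). NB has no
#' tuned hyperparameters (empty grid).
#'
#' @param family One of `"RF"`, `"SVM"`, `"LR"`, `"DT"`, `"NB"`, `"KNN"`.
#' @return A data.frame with one row per candidate (0 rows for NB).
#' @export
model_grid <- function(family = c("RF", "SVM", "LR", "DT", "NB", "KNN")) {
  family <- match.arg(family)
  switch(family,
    RF = expand.grid(n_estimators = c(50, 100, 200),
                     max_depth = c(NA, 10, 20, 30),
                     min_samples_split = c(2, 5, 10),
                     min_samples_leaf = c(1, 2, 4)),
    SVM = expand.grid(C = c(0.1, 1, 10, 100),
                      kernel = c("linear", "rbf"),
                      gamma = c("scale", "auto"),
                      stringsAsFactors = FALSE),
    LR = expand.grid(C = c(0.01, 0.1, 1, 10, 100),
                     penalty = c("l1", "l2"),
                     stringsAsFactors = FALSE),
    DT = expand.grid(max_depth = c(NA, 10, 20, 30),
                     min_samples_split = c(2, 5, 10),
                     min_samples_leaf = c(1, 2, 4),
                     criterion = c("gini", "entropy"),
                     stringsAsFactors = FALSE),
    NB = data.frame(),
    KNN = expand.grid(n_neighbors = c(3, 5, 7, 9),
                      weights = c("uniform", "distance"),
                      metric = c("euclidean", "manhattan"),
                      stringsAsFactors = FALSE))
}

# Fit one family with one parameter setting. Returns an `rcads_model`.
fit_model <- function(family, X, y, params = NULL, seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  yf <- factor(as.character(y), levels = classes)
  p <- ncol(X)
  params <- as.list(params)
  fit <- switch(family,
    RF = ranger::ranger(
      x = X, y = yf,
      num.trees = params$n_estimators %||% 100,
      max.depth = if (is.null(params$max_depth) || is.na(params$max_depth)) 0 else params$max_depth,
      min.node.size = params$min_samples_split %||% 2,
      min.bucket = params$min_samples_leaf %||% 1,
      seed = seed, num.threads = 1L),
    SVM = {
      gamma_mode <- params$gamma %||% "scale"
      gamma <- if (identical(gamma_mode, "auto")) 1 / p
               else 1 / (p * max(stats::var(as.vector(X)), 1e-12))
      e1071::svm(x = X, y = yf,
                 cost = params$C %||% 1,
                 kernel = if (identical(params$kernel %||% "rbf", "rbf")) "radial" else "linear",
                 gamma = gamma, scale = FALSE)
    },
    LR = {
      lam <- 1 / ((params$C %||% 1) * nrow(X))
      glmnet::glmnet(X, yf, family = "multinomial",
                     alpha = if (identical(params$penalty %||% "l2", "l1")) 1 else 0,
                     lambda = lam)
    },
    DT = rpart::rpart(
      y ~ ., data = data.frame(y = yf, X, check.names = FALSE),
      method = "class",
      parms = list(split = if (identical(params$criterion %||% "gini", "entropy"))
        "information" else "gini"),
      control = rpart::rpart.control(
        maxdepth = if (is.null(params$max_depth) || is.na(params$max_depth)) 30 else params$max_depth,
        minsplit = params$min_samples_split %||% 2,
        minbucket = params$min_samples_leaf %||% 1,
        cp = 0, xval = 0)),
    NB = e1071::naiveBayes(x = as.data.frame(X), y = yf),
    KNN = list(X = X, y = yf,
               k = params$n_neighbors %||% 5,
               weights = params$weights %||% "uniform",
               metric = params$metric %||% "euclidean"),
    stop("unknown model family: ", family))
  structure(list(family = family, fit = fit, params = params,
                 features = colnames(X), classes = classes, seed = seed),
            class = "rcads_model")
}

# Distance-weighted k-NN prediction (euclidean or manhattan).
knn_predict <- function(obj, Xnew) {
  pred <- character(nrow(Xnew))
  cls <- levels(obj$y)
  for (i in seq_len(nrow(Xnew))) {
    d <- if (obj$metric == "manhattan") {
      colSums(abs(t(obj$X) - Xnew[i, ]))
    } else {
      sqrt(colSums((t(obj$X) - Xnew[i, ])^2))
    }
    nn <- order(d)[seq_len(min(obj$k, length(d)))]
    w <- if (obj$weights == "distance") 1 / pmax(d[nn], 1e-12) else rep(1, length(nn))
    votes <- vapply(cls, function(cl) sum(w[obj$y[nn] == cl]), numeric(1))
    pred[i] <- cls[which.max(votes)]
  }
  factor(pred, levels = cls)
}

#' @export
predict.rcads_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  out <- switch(object$family,
    RF = stats::predict(object$fit, data = X, num.threads = 1L)$predictions,
    SVM = stats::predict(object$fit, X),
    LR = {
      cl <- stats::predict(object$fit, newx = X, type = "class",
                           s = object$fit$lambda[1])
      factor(as.character(cl), levels = object$classes)
    },
    DT = stats::predict(object$fit, data.frame(X, check.names = FALSE), type = "class"),
    NB = stats::predict(object$fit, as.data.frame(X)),
    KNN = knn_predict(object$fit, X))
  factor(as.character(out), levels = object$classes)
}

#' Grid search with stratified cross-validation
#'
#' Exhaustive search over the family's grid (see [model_grid()]): each
#' candidate is scored by mean fold accuracy under stratified k-fold CV,
#' ties are broken by grid order (first candidate wins), and the winner is
#' refit on the full training set. NB has no grid and is fit directly (its
#' CV scores are still computed for model comparison); an empty grid for any
#' other family is an error.
#'
#' @param X Training feature matrix.
#' @param y Training labels.
#' @param family Model family, see [model_grid()].
#' @param folds Number of CV folds (default 5); must not exceed the smallest
#'   class count.
#' @param seed Integer seed (fold assignment and model fitting).
#' @param grid Optional custom grid (data.frame, one row per candidate).
#' @return A list with `model` (refit `rcads_model`), `best_params`,
#'   `cv_mean_accuracy` and `cv_fold_scores` (fold accuracies of the best
#'   candidate).
#' @export
grid_search_cv <- function(X, y, family, folds = 5L, seed = 1L, grid = NULL) {
  X <- as.matrix(X)
  grid <- grid %||% model_grid(family)
  if (nrow(grid) == 0L && family != "NB") stop("empty hyperparameter grid for family ", family)
  counts <- table(y)
  if (min(counts) < folds) {
    stop(sprintf("smallest class has %d member(s); cannot run %d-fold stratified CV",
                 min(counts), folds))
  }
  set.seed(seed)
  fold_id <- stratified_folds(y, folds)
  score <- function(params) {
    vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- fit_model(family, X[tr, , drop = FALSE], y[tr], params, seed = seed)
      mean(as.character(predict(m, X[!tr, , drop = FALSE])) == as.character(y[!tr]))
    }, numeric(1))
  }
  if (nrow(grid) == 0L) {
    fold_scores <- score(NULL)
    best_params <- list()
  } else {
    means <- numeric(nrow(grid))
    all_scores <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      all_scores[[i]] <- score(grid[i, , drop = FALSE])
      means[i] <- mean(all_scores[[i]])
    }
    best <- which.max(means)  # first maximum: grid-order tie-break
    best_params <- as.list(grid[best, , drop = FALSE])
    fold_scores <- all_scores[[best]]
  }
  model <- fit_model(family, X, y, best_params, seed = seed)
  list(model = model, best_params = best_params,
       cv_mean_accuracy = mean(fold_scores), cv_fold_scores = fold_scores)
}

#' Per-class metrics from a confusion matrix
#'
#' Precision, recall and F1 per class (0 when undefined, with a warning for
#' classes never predicted), overall accuracy, and macro (unweighted) and
#' weighted (support-weighted) averages.
#'
#' @param confusion Square count matrix, rows = truth, columns = predicted,
#'   identically ordered.
#' @return A list with `per_class` (data.frame), `accuracy`, `macro_avg`,
#'   `weighted_avg`, `confusion`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  tp <- diag(confusion)
  never <- predicted == 0 & support > 0
  if (any(never)) {
    warning("class(es) never predicted; precision set to 0: ",
            paste(rownames(confusion)[never], collapse = ", "))
  }
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = rownames(confusion) %||% as.character(seq_len(nrow(confusion)) - 1L),
                          precision = precision, recall = recall, f1 = f1,
                          support = support, row.names = NULL)
  wavg <- function(v) sum(v * support) / sum(support)
  list(per_class = per_class,
       accuracy = sum(tp) / sum(confusion),
       macro_avg = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
       weighted_avg = c(precision = wavg(precision), recall = wavg(recall), f1 = wavg(f1)),
       confusion = confusion)
}

#' Evaluate a fitted model on test data
#'
#' Predicts the test set and reports per-class precision/recall/F1, accuracy,
#' macro and weighted averages and the confusion matrix.
#'
#' @param model An `rcads_model` from [grid_search_cv()] or `fit_model`.
#' @param X_test,y_test Test features and labels (labels must be 0/1/2).
#' @param cv_fold_scores,best_params Optional bookkeeping carried into the
#'   report.
#' @return An object of class `rcads_eval`.
#' @export
evaluate_model <- function(model, X_test, y_test, cv_fold_scores = NULL,
                           best_params = NULL) {
  if (!all(as.character(y_test) %in% c("0", "1", "2"))) {
    stop("test labels outside {0, 1, 2}")
  }
  pred <- predict(model, X_test)
  lev <- c("0", "1", "2")
  confusion <- table(factor(as.character(y_test), levels = lev),
                     factor(as.character(pred), levels = lev))
  confusion <- matrix(confusion, 3, 3, dimnames = list(truth = lev, predicted = lev))
  m <- metrics_from_confusion(confusion)
  structure(c(m, list(cv_fold_scores = cv_fold_scores,
                      best_params = best_params, family = model$family)),
            class = "rcads_eval")
}

#' @export
print.rcads_eval <- function(x, digits = 2, ...) {
  cat(sprintf("Evaluation%s\n", if (!is.null(x$family)) paste0(" (", x$family, ")") else ""))
  tab <- x$per_class
  tab[, 2:4] <- round(tab[, 2:4], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("accuracy          %.*f\n", digits, x$accuracy))
  cat(sprintf("macro average     %s\n",
              paste(sprintf("%.*f", digits, x$macro_avg), collapse = " ")))
  cat(sprintf("weighted average  %s\n",
              paste(sprintf("%.*f", digits, x$weighted_avg), collapse = " ")))
  cat("confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Paired comparison of two models' CV fold scores
#'
#' Two-sided paired t-test on fold accuracies, paired by fold. All-zero
#' differences return p = 1 with a note (the models are indistinguishable);
#' nonzero constant differences have zero variance and are an error.
#'
#' @param fold_scores_a,fold_scores_b Equal-length (>= 2) fold accuracy
#'   vectors.
#' @return A list with `t_statistic`, `p_value` and possibly `note`.
#' @export
compare_models <- function(fold_scores_a, fold_scores_b) {
  stopifnot(length(fold_scores_a) == length(fold_scores_b),
            length(fold_scores_a) >= 2L)
  d <- fold_scores_a - fold_scores_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t_statistic = 0, p_value = 1,
                  note = "all fold differences zero"))
    }
    stop("fold differences are constant and nonzero; paired t-test undefined")
  }
  tt <- stats::t.test(fold_scores_a, fold_scores_b, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' External validation of a frozen model on a new cohort
#'
#' Scores and labels the cohort against the norm table (the truth labels),
#' predicts with the already-fitted model, and returns the full evaluation
#' report including the confusion matrix.
#'
#' @param model A fitted `rcads_model`.
#' @param cohort A complete `rcads_cohort`.
#' @param bank An [rcads_item_bank()].
#' @param norms An [norm_table()].
#' @return An `rcads_eval` report.
#' @export
external_validate <- function(model, cohort, bank = rcads_item_bank(), norms) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0L) stop("empty external cohort")
  cols <- c("sex", "grade", item_cols())
  bad <- which(!stats::complete.cases(df[, cols]))
  if (length(bad)) {
    stop("unscorable record(s) in external cohort (missing values) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  scored <- if ("label" %in% names(df)) df else score_cohort(cohort, bank, norms)
  X <- as.matrix(scored[, model$features, drop = FALSE])
  evaluate_model(model, X, scored$label)
}
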