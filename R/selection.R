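# Per-item association screening and consensus feature elimination.
#
# Three routes flag uninformative items: a chi-square test of independence
# between item level and class label, a Spearman rank correlation between
# item level and the ordinal label, and random-forest recursive feature
# elimination (RF-RFE). An item is eliminated only when all three agree.

#' Chi-square test of independence between an item and the class label
#'
#' Pearson chi-square on the observed item-by-label contingency table,
#' without continuity correction. When any cell expectation is below 5 the
#' test is still performed and the number of such cells is attached as
#' attribute `low_expected` (sparse tables are unavoidable at clinic sample
#' sizes; a warning is emitted rather than silently switching tests).
#'
#' @param item Integer vector of response levels.
#' @param label Class vector (any discrete type).
#' @return The two-sided p-value, with attributes `statistic`, `df`,
#'   `low_expected`.
#' @export
item_chisq <- function(item, label) {
  stopifnot(length(item) == length(label))
  tab <- table(item, label)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("degenerate contingency table: need >= 2 observed levels and >= 2 classes")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- sum(res$expected < 5)
  if (low > 0) warning(sprintf("%d cell(s) with expected count < 5", low))
  structure(unname(res$p.value), statistic = unname(res$statistic),
            df = unname(res$parameter), low_expected = low)
}

#' Spearman association between an item and the ordinal label
#'
#' Spearman rho with average-rank ties; the p-value uses the large-sample t
#' approximation.
#'
#' @param item Integer vector of response levels.
#' @param label Ordinal label vector (0/1/2).
#' @return A list with `rho` and `p_value`.
#' @export
item_spearman <- function(item, label) {
  stopifnot(length(item) == length(label), length(item) >= 3L)
  if (stats::sd(item) == 0 || stats::sd(label) == 0) {
    stop("constant input: Spearman correlation undefined")
  }
  res <- suppressWarnings(
    stats::cor.test(as.numeric(item), as.numeric(label),
                    method = "spearman", exact = FALSE))
  list(rho = unname(res$estimate), p_value = res$p.value)
}

#' Random-forest recursive feature elimination
#'
#' Ranks features by random-forest impurity importance, removing one feature
#' per step. At each subset size the mean stratified cross-validated accuracy
#' is recorded; the returned feature set is the one whose size maximises mean
#' CV accuracy (ties broken in favour of the smaller set), so the number of
#' selected features is determined automatically rather than fixed in
#' advance. Deterministic under a fixed seed.
#'
#' @param X Numeric feature matrix (columns named).
#' @param y Class labels.
#' @param cv_folds Number of stratified CV folds (default 5).
#' @param num_trees Trees per forest (default 100).
#' @param seed Integer seed.
#' @return A list with `selected` (character feature names),
#'   `cv_accuracy` (mean CV accuracy of the selected set) and `path`
#'   (data.frame of subset size vs mean CV accuracy).
#' @export
rf_rfe <- function(X, y, cv_folds = 5L, num_trees = 100L, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (n <= cv_folds) stop("too few records for ", cv_folds, "-fold CV")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  set.seed(seed)
  folds <- stratified_folds(y, cv_folds)
  cv_accuracy <- function(cols) {
    acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      if (!any(!tr)) return(NA_real_)
      fit <- ranger::ranger(x = X[tr, cols, drop = FALSE], y = y[tr],
                            num.trees = num_trees, seed = seed,
                            num.threads = 1L)
      pred <- stats::predict(fit, data = X[!tr, cols, drop = FALSE],
                             num.threads = 1L)$predictions
      mean(pred == y[!tr])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }

  active <- colnames(X)
  sizes <- integer(0); accs <- numeric(0); sets <- list()
  while (length(active) >= 1L) {
    sizes <- c(sizes, length(active))
    accs <- c(accs, cv_accuracy(active))
    sets[[length(sets) + 1L]] <- active
    if (length(active) == 1L) break
    fit <- ranger::ranger(x = X[, active, drop = FALSE], y = y,
                          num.trees = num_trees, importance = "impurity",
                          seed = seed, num.threads = 1L)
    imp <- fit$variable.importance
    active <- setdiff(active, names(which.min(imp)))
  }
  # Best mean CV accuracy; among ties, the smallest subset.
  best <- which(accs == max(accs))
  best <- best[which.min(sizes[best])]
  list(selected = sets[[best]], cv_accuracy = accs[best],
       path = data.frame(size = sizes, cv_accuracy = accs))
}

#' Consensus feature elimination
#'
#' An item is eliminated only when all three screens agree that it is
#' uninformative: chi-square p above `alpha`, Spearman p above `alpha`, and
#' exclusion from the RF-RFE selected set.
#'
#' @param items Character vector of item names screened.
#' @param chisq_p Named numeric vector of chi-square p-values.
#' @param spearman_p Named numeric vector of Spearman p-values.
#' @param rfe_selected Character vector of RF-RFE-selected items.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of eliminated items (possibly empty).
#' @export
consensus_eliminate <- function(items, chisq_p, spearman_p, rfe_selected,
                                alpha = 0.05) {
  if (!length(items)) return(character(0))
  stopifnot(all(items %in% names(chisq_p)), all(items %in% names(spearman_p)))
  items[chisq_p[items] > alpha & spearman_p[items] > alpha &
          !(items %in% rfe_selected)]
}

#' Run all three screens and the consensus rule on a scored cohort
#'
#' @param scored A scored cohort data.frame (from [score_cohort()]) with the
#'   `label` column.
#' @param alpha Significance level for both filter methods.
#' @param cv_folds,num_trees,seed Passed to [rf_rfe()].
#' @return An object of class `rcads_selection`: per-item chi-square
#'   p-values, Spearman rho/p, the RF-RFE selection with its CV accuracy,
#'   and the consensus-eliminated set.
#' @export
select_features <- function(scored, alpha = 0.05, cv_folds = 5L,
                            num_trees = 100L, seed = 1L) {
  X <- item_matrix(scored)
  y <- scored$label
  cols <- colnames(X)
  chisq_p <- stats::setNames(vapply(cols, function(cl) {
    as.numeric(suppressWarnings(item_chisq(X[, cl], y)))
  }, numeric(1)), cols)
  sp <- lapply(cols, function(cl) item_spearman(X[, cl], y))
  spearman_rho <- stats::setNames(vapply(sp, `[[`, numeric(1), "rho"), cols)
  spearman_p <- stats::setNames(vapply(sp, `[[`, numeric(1), "p_value"), cols)
  rfe <- rf_rfe(X, y, cv_folds = cv_folds, num_trees = num_trees, seed = seed)
  eliminated <- consensus_eliminate(cols, chisq_p, spearman_p, rfe$selected,
                                    alpha = alpha)
  structure(list(chisq_p = chisq_p, spearman_rho = spearman_rho,
                 spearman_p = spearman_p, rfe_selected = rfe$selected,
                 rfe_cv_accuracy = rfe$cv_accuracy, rfe_path = rfe$path,
                 eliminated = eliminated, alpha = alpha),
            class = "rcads_selection")
}

#' @export
print.rcads_selection <- function(x, ...) {
  cat(sprintf("Feature screening at alpha = %.2f\n", x$alpha))
  cat(sprintf("  chi-square:  %d item(s) not significant\n", sum(x$chisq_p > x$alpha)))
  cat(sprintf("  Spearman:    %d item(s) not significant\n", sum(x$spearman_p > x$alpha)))
  cat(sprintf("  RF-RFE:      %d of %d items selected (CV accuracy %.3f)\n",
              length(x$rfe_selected), length(x$chisq_p), x$rfe_cv_accuracy))
  cat("  consensus-eliminated:",
      if (length(x$eliminated)) paste(x$eliminated, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
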