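# Internal-consistency analysis: Cronbach's alpha, alpha-if-item-deleted,
# inter-item correlation summaries.

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var(total))` with sample variances
#' (n-1 denominator). Undefined (error) when the total score has zero
#' variance.
#'
#' @param responses Numeric matrix or data.frame, records in rows, items in
#'   columns; no missing values.
#' @param item_set Optional column selection (names or indices).
#' @return The alpha coefficient (a real number, at most 1).
#' @export
cronbach_alpha <- function(responses, item_set = NULL) {
  X <- as.matrix(responses)
  if (!is.null(item_set)) X <- X[, item_set, drop = FALSE]
  if (anyNA(X)) stop("responses must be complete")
  k <- ncol(X)
  if (k < 2L || nrow(X) < 2L) stop("need at least 2 items and 2 records")
  vt <- stats::var(rowSums(X))
  if (vt <= .Machine$double.eps) stop("total score has zero variance; alpha undefined")
  vi <- apply(X, 2, stats::var)
  k / (k - 1) * (1 - sum(vi) / vt)
}

#' Alpha if item deleted
#'
#' Cronbach's alpha of the remaining k-1 items after deleting each item in
#' turn.
#'
#' @inheritParams cronbach_alpha
#' @return Named numeric vector, one entry per item.
#' @export
alpha_if_deleted <- function(responses, item_set = NULL) {
  X <- as.matrix(responses)
  if (!is.null(item_set)) X <- X[, item_set, drop = FALSE]
  if (ncol(X) < 3L) stop("alpha-if-deleted needs at least 3 items")
  cols <- colnames(X) %||% as.character(seq_len(ncol(X)))
  stats::setNames(
    vapply(seq_len(ncol(X)), function(j) cronbach_alpha(X[, -j, drop = FALSE]),
           numeric(1)),
    cols)
}

#' Pairwise inter-item correlation summary
#'
#' Mean, minimum and maximum of the pairwise Spearman correlations (average
#' ranks for ties) over all item pairs. Pairs involving a constant item are
#' undefined and excluded, with a warning giving the count.
#'
#' @inheritParams cronbach_alpha
#' @return A list with `mean`, `min`, `max`, `n_pairs` (used pairs) and
#'   `n_undefined` (excluded pairs).
#' @export
interitem_summary <- function(responses, item_set = NULL) {
  X <- as.matrix(responses)
  if (!is.null(item_set)) X <- X[, item_set, drop = FALSE]
  if (anyNA(X)) stop("responses must be complete")
  k <- ncol(X)
  if (k < 2L) stop("need at least 2 items")
  R <- suppressWarnings(stats::cor(X, method = "spearman"))
  vals <- R[upper.tri(R)]
  n_undef <- sum(is.na(vals))
  if (n_undef > 0) {
    warning(sprintf("%d item pair(s) with a constant item excluded from the summary", n_undef))
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no defined item pairs")
  list(mean = mean(vals), min = min(vals), max = max(vals),
       n_pairs = length(vals), n_undefined = n_undef)
}

#' Reliability report for a scored cohort
#'
#' Cronbach's alpha for the overall internalizing scale (all 47 items), the
#' overall anxiety scale (all items outside MDD), and each of the six
#' subscales; alpha-if-item-deleted for the overall scale; and the
#' inter-item correlation summary.
#'
#' @param cohort A complete `rcads_cohort`.
#' @param bank An [rcads_item_bank()].
#' @return An object of class `rcads_reliability`.
#' @export
reliability_report <- function(cohort, bank = rcads_item_bank()) {
  X <- item_matrix(cohort)
  if (anyNA(X)) stop("cohort contains missing item responses; filter_complete() first")
  scales <- c(list(internalizing = 1:47,
                   anxiety = bank_items(bank, setdiff(SUBSCALES, "MDD"))),
              bank_blocks(bank))
  alpha_by_scale <- vapply(scales, function(ids) {
    cronbach_alpha(X[, item_cols(ids), drop = FALSE])
  }, numeric(1))
  out <- list(alpha_overall = alpha_by_scale[["internalizing"]],
              alpha_by_scale = alpha_by_scale,
              alpha_if_deleted = alpha_if_deleted(X),
              interitem = interitem_summary(X))
  structure(out, class = "rcads_reliability")
}

#' @export
print.rcads_reliability <- function(x, ...) {
  cat("Internal consistency (Cronbach's alpha)\n")
  tab <- data.frame(scale = names(x$alpha_by_scale),
                    alpha = round(unname(x$alpha_by_scale), 3))
  print(tab, row.names = FALSE)
  cat(sprintf("Inter-item Spearman correlations: mean %.3f, range [%.3f, %.3f]\n",
              x$interitem$mean, x$interitem$min, x$interitem$max))
  invisible(x)
}
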