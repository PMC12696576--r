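# Raw scoring, normative T-score conversion, three-class labelling.

#' Construct a normative table
#'
#' A norm table holds, per (grade, sex) cell, the reference mean and standard
#' deviation of the total internalizing raw score used for T-score conversion
#' (`T = 50 + 10 * (raw - mean) / sd`). Official published norms are not
#' shipped; tables are either supplied by the user or built from a simulated
#' reference population with [build_norms()]. Grade bands default to single
#' grades; a coarser banding is expressed by repeating rows.
#'
#' @param entries A data.frame with columns `grade`, `sex`, `mean`, `sd`
#'   covering every (grade 2-12, sex) cell exactly once.
#' @return An object of class `rcads_norms`.
#' @export
norm_table <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("grade", "sex", "mean", "sd") %in% names(entries)))
  if (any(entries$sd <= 0)) stop("norm table sd entries must be > 0")
  key <- paste(entries$grade, entries$sex)
  if (anyDuplicated(key)) stop("duplicate (grade, sex) entries in norm table")
  need <- as.vector(outer(2:12, c("boy", "girl"), paste))
  absent <- setdiff(need, key)
  if (length(absent)) stop("norm table misses cells: ", paste(absent, collapse = "; "))
  structure(list(entries = entries[, c("grade", "sex", "mean", "sd")]),
            class = "rcads_norms")
}

#' @export
print.rcads_norms <- function(x, ...) {
  cat("RCADS norm table (total internalizing raw score):\n")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

norm_lookup <- function(norms, grade, sex) {
  e <- norms$entries
  idx <- match(paste(grade, sex), paste(e$grade, e$sex))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("no norm entry for grade %s, sex %s", grade[bad], sex[bad]))
  }
  e[idx, ]
}

#' Classify a T-score into Normal / Borderline / Clinical
#'
#' Thresholds: `t < 65` Normal (0), `65 <= t < 70` Borderline (1), `t >= 70`
#' Clinical (2). The three labels partition the real line.
#'
#' @param t Numeric vector of T-scores.
#' @return Integer labels 0/1/2.
#' @export
classify_tscore <- function(t) {
  ifelse(t < 65, 0L, ifelse(t < 70, 1L, 2L))
}

#' Score a cohort
#'
#' Computes per-record raw totals (sum of the 47 responses), per-subscale raw
#' sums, the T-score against the (grade, sex) norm entry, and the three-class
#' label (see [classify_tscore()]). Classification uses the total
#' internalizing score only.
#'
#' @param cohort A complete `rcads_cohort` (no missing values; see
#'   [filter_complete()]).
#' @param bank An [rcads_item_bank()].
#' @param norms An [norm_table()].
#' @return A data.frame: the cohort columns plus `raw_total`, one `raw_<sub>`
#'   column per subscale, `t_score` and `label`.
#' @export
score_cohort <- function(cohort, bank = rcads_item_bank(), norms) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0L) stop("cannot score an empty cohort")
  cols <- c("sex", "grade", item_cols())
  if (any(!stats::complete.cases(df[, cols]))) {
    stop("cohort contains missing values; filter_complete() first")
  }
  X <- item_matrix(df)
  out <- df
  out$raw_total <- as.integer(rowSums(X))
  for (s in SUBSCALES) {
    out[[paste0("raw_", tolower(s))]] <-
      as.integer(rowSums(X[, item_cols(bank_items(bank, s)), drop = FALSE]))
  }
  e <- norm_lookup(norms, df$grade, df$sex)
  out$t_score <- 50 + 10 * (out$raw_total - e$mean) / e$sd
  out$label <- classify_tscore(out$t_score)
  out
}

#' Compare raw scores of retained and dropped records
#'
#' Welch two-sample t-test of the total raw scores between the records
#' retained by listwise deletion and those dropped, to check that deletion
#' did not select on symptom severity. Raw totals are computed on records
#' whose 47 items are all present (records dropped for missing sex/grade
#' still contribute); records with missing items are excluded from this
#' comparison.
#'
#' @param retained,dropped `rcads_cohort` objects from [filter_complete()].
#' @return A list with `t_statistic`, `p_value`, `df` and the usable group
#'   sizes `n_retained`, `n_dropped`.
#' @export
compare_retained_dropped <- function(retained, dropped) {
  totals <- function(cohort) {
    X <- item_matrix(cohort)
    ok <- stats::complete.cases(X)
    rowSums(X[ok, , drop = FALSE])
  }
  a <- totals(retained)
  b <- totals(dropped)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 records with complete item responses")
  }
  tt <- stats::t.test(a, b)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n_retained = length(a), n_dropped = length(b))
}
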