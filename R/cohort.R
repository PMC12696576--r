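# Cohort container and CSV I/O.
#
# A cohort is a data.frame with columns sex ("boy"/"girl" or NA), grade
# (integer 2-12 or NA) and item_01..item_47 (integer 0-3 or NA), carrying
# provenance ("real", "synthetic" or "hybrid"), an optional seed and, for
# hybrid cohorts, the originating augmentation ratio, as attributes.

new_cohort <- function(df, provenance = c("real", "synthetic", "hybrid"),
                       seed = NULL, ratio = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df,
            provenance = provenance, seed = seed, ratio = ratio,
            class = c("rcads_cohort", "data.frame"))
}

cohort_provenance <- function(cohort) attr(cohort, "provenance") %||% "real"

#' @export
print.rcads_cohort <- function(x, ...) {
  cat(sprintf("RCADS cohort: %d records (%s)\n", nrow(x), cohort_provenance(x)))
  if (!is.null(attr(x, "ratio"))) cat(sprintf("  augmentation ratio 1:%d\n", attr(x, "ratio")))
  miss <- sum(!stats::complete.cases(x))
  cat(sprintf("  records with missing values: %d\n", miss))
  invisible(x)
}

# Default sex aliases (case-insensitive): values are canonical codes.
default_sex_aliases <- function() {
  c(boy = "boy", girl = "girl", m = "boy", f = "girl",
    male = "boy", female = "girl", b = "boy", g = "girl")
}

#' Read a cohort from CSV
#'
#' Reads a response file with header `sex,grade,item_01,...,item_47`. Empty
#' cells denote missing values. Item responses are validated against the item
#' bank's levels; malformed files are rejected with row/column diagnostics.
#'
#' @param path CSV path, UTF-8, one record per row.
#' @param bank An [rcads_item_bank()].
#' @param sex_aliases Named character vector mapping accepted (lower-cased)
#'   sex codes to `"boy"`/`"girl"`.
#' @return An object of class `rcads_cohort` with provenance `"real"`.
#' @export
read_cohort <- function(path, bank = rcads_item_bank(),
                        sex_aliases = default_sex_aliases()) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  dup <- header[duplicated(header)]
  if (length(dup)) stop("duplicate column(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  expected <- c("sex", "grade", item_cols())
  unknown <- setdiff(header, expected)
  if (length(unknown)) stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  absent <- setdiff(expected, header)
  if (length(absent)) stop("missing column(s) in ", path, ": ", paste(absent, collapse = ", "))

  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character", check.names = FALSE)
  df <- df[, expected]

  sex_raw <- tolower(trimws(df$sex))
  sex <- unname(sex_aliases[sex_raw])
  bad_sex <- which(!is.na(sex_raw) & is.na(sex))
  if (length(bad_sex)) {
    stop(sprintf("invalid sex value '%s' at row %d", sex_raw[bad_sex[1]], bad_sex[1]))
  }

  parse_int <- function(v, col, allowed) {
    out <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(out) | !(out %in% allowed)))
    if (length(bad)) {
      stop(sprintf("invalid value '%s' in column %s at row %d (allowed: %s)",
                   v[bad[1]], col, bad[1], paste(range(allowed), collapse = "-")))
    }
    out
  }
  grade <- parse_int(df$grade, "grade", 2:12)
  items <- lapply(item_cols(), function(cl) parse_int(df[[cl]], cl, bank$levels))
  out <- data.frame(sex = sex, grade = grade, stringsAsFactors = FALSE)
  out[item_cols()] <- items
  new_cohort(out, "real")
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, so complete
#' cohorts round-trip bit-exactly.
#'
#' @param cohort An `rcads_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, c("sex", "grade", item_cols())],
                   path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Listwise-delete incomplete records
#'
#' Splits a cohort into the records with no missing value in sex, grade or
#' any of the 47 items (retained) and the rest (dropped). The operation is
#' idempotent on the retained part.
#'
#' @param cohort An `rcads_cohort`.
#' @return A list with `rcads_cohort` elements `retained` and `dropped`.
#' @export
filter_complete <- function(cohort) {
  cols <- c("sex", "grade", item_cols())
  ok <- stats::complete.cases(as.data.frame(cohort)[, cols])
  prov <- cohort_provenance(cohort)
  list(retained = new_cohort(as.data.frame(cohort)[ok, , drop = FALSE], prov),
       dropped  = new_cohort(as.data.frame(cohort)[!ok, , drop = FALSE], prov))
}

# Item response matrix (n x 47, integer) from a cohort.
item_matrix <- function(cohort, items = 1:47) {
  as.matrix(as.data.frame(cohort)[, item_cols(items), drop = FALSE])
}

#' Class-distribution summaries in the questionnaire-report style
#'
#' `cohort_summary_by_sex()` tabulates labelled records by sex with
#' largest-remainder integer percentages per row; `cohort_summary_by_grade()`
#' tabulates by grade with one-decimal (truncated) percentages. Both expect
#' the `label` column added by [score_cohort()].
#'
#' @param scored A scored cohort data.frame containing `sex`, `grade`,
#'   `label`.
#' @return A data.frame with counts `n_*` and percentages `pct_*` per class
#'   plus a `total` column.
#' @export
cohort_summary_by_sex <- function(scored) {
  stopifnot("label" %in% names(scored))
  groups <- c(boy = "boy", girl = "girl")
  rows <- lapply(names(groups), function(g) {
    sub <- scored[!is.na(scored$sex) & scored$sex == groups[[g]], ]
    counts <- vapply(0:2, function(k) sum(sub$label == k), integer(1))
    pct <- if (sum(counts) > 0) percent_integer(counts) else rep(NA_real_, 3)
    data.frame(group = g, n_normal = counts[1], pct_normal = pct[1],
               n_borderline = counts[2], pct_borderline = pct[2],
               n_clinical = counts[3], pct_clinical = pct[3],
               total = sum(counts), stringsAsFactors = FALSE)
  })
  counts <- vapply(0:2, function(k) sum(scored$label == k), integer(1))
  pct <- percent_integer(counts)
  rows <- c(rows, list(data.frame(
    group = "total", n_normal = counts[1], pct_normal = pct[1],
    n_borderline = counts[2], pct_borderline = pct[2],
    n_clinical = counts[3], pct_clinical = pct[3],
    total = sum(counts), stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' @rdname cohort_summary_by_sex
#' @export
cohort_summary_by_grade <- function(scored) {
  stopifnot("label" %in% names(scored))
  grades <- sort(unique(scored$grade[!is.na(scored$grade)]))
  rows <- lapply(grades, function(g) {
    sub <- scored[!is.na(scored$grade) & scored$grade == g, ]
    counts <- vapply(0:2, function(k) sum(sub$label == k), integer(1))
    data.frame(group = as.character(g),
               n_normal = counts[1], pct_normal = percent_one_decimal(counts[1], sum(counts)),
               n_borderline = counts[2], pct_borderline = percent_one_decimal(counts[2], sum(counts)),
               n_clinical = counts[3], pct_clinical = percent_one_decimal(counts[3], sum(counts)),
               total = sum(counts), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
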