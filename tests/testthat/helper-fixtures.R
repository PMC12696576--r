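# Shared fixtures, built in code at test time.

# A generator configuration without demographic missingness.
complete_config <- function(n, seed = 1L, ...) {
  cohort_config(n = n, missing_sex = 0L, missing_grade = 0L, missing_both = 0L,
                seed = seed, ...)
}

# A flat norm table (same mean/sd for every cell), handy when the test only
# needs well-defined T-scores.
flat_norms <- function(mean = 40, sd = 14) {
  norm_table(data.frame(expand.grid(grade = 2:12, sex = c("boy", "girl"),
                                    stringsAsFactors = FALSE),
                        mean = mean, sd = sd))
}

# Norm table built once from the default generator; reused across tests.
shared_norms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_norms(cohort_config(), seed = 77L)
    cache
  }
})

# A small complete cohort data.frame with arbitrary but valid fields.
manual_cohort <- function(X, sex = NULL, grade = NULL) {
  n <- nrow(X)
  df <- data.frame(sex = sex %||% rep(c("boy", "girl"), length.out = n),
                   grade = grade %||% rep(2:12, length.out = n),
                   stringsAsFactors = FALSE)
  stopifnot(ncol(X) == 47)
  colnames(X) <- sprintf("item_%02d", 1:47)
  df[colnames(X)] <- as.data.frame(X)
  rcadscreen:::new_cohort(df, "real")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
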