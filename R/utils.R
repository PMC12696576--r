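# Internal helpers shared across modules.

# Canonical item column names: item_01 ... item_47.
item_cols <- function(ids = 1:47) sprintf("item_%02d", ids)

SUBSCALES <- c("MDD", "GAD", "OCD", "PD", "SAD", "SP")
CLASS_LABELS <- c("Normal", "Borderline", "Clinical")

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a 32-bit seed, so
#' that pipeline stages draw from independent, reproducible streams.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer(((abs(master) %% 65011) * 33013 + h * 97 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified fold assignment: every class spread as evenly as possible over
# folds. Returns an integer vector of fold ids.
stratified_folds <- function(y, folds) {
  y <- as.character(y)
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

# Largest-remainder integer percentages: floors topped up (largest fractional
# part first) until the row sums to 100.
percent_integer <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  p <- 100 * counts / sum(counts)
  out <- floor(p)
  short <- 100 - sum(out)
  if (short > 0) {
    bump <- order(p - out, decreasing = TRUE)[seq_len(short)]
    out[bump] <- out[bump] + 1
  }
  as.numeric(out)
}

# One-decimal percentage, truncated (not rounded).
percent_one_decimal <- function(n, total) {
  stopifnot(total > 0)
  floor(1000 * n / total) / 10
}
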