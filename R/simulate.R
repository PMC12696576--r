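# Synthetic-cohort generator.
#
# Emulates a small clinic cohort: one latent severity per subject (shifted by
# the drawn class), items generated by a thresholded one-factor model per
# subscale, demographics drawn from configurable margins, and MCAR
# missingness restricted to sex/grade. Ground truth (exact item marginals,
# exact within-subscale Spearman correlations, drawn classes) accompanies
# every cohort so downstream estimators can be checked by parameter recovery.

# Default per-item latent cutpoints: a common base with a deterministic
# per-item offset cycle, so marginals vary across items but are reproducible
# without randomness.
default_thresholds <- function() {
  base <- c(0.2, 1.0, 1.8)
  offsets <- c(-0.3, -0.15, 0, 0.15, 0.3)
  t(vapply(1:47, function(i) base + offsets[(i - 1L) %% 5L + 1L], numeric(3)))
}

# Grade distribution proportional to the clinic margin used throughout the
# package's examples (grades 2-12).
default_grade_probs <- function() {
  counts <- c(1, 6, 6, 2, 12, 13, 12, 16, 13, 3, 5)
  stats::setNames(counts / sum(counts), 2:12)
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the clinic cohort the package's examples are built
#' around: 138 records, class mix 55/7/38 percent
#' (Normal/Borderline/Clinical), 38/62 boy/girl mix, grades 2-12 with a
#' clinic-like margin, moderate within-subscale inter-item correlation
#' (loading 0.55), and missing-completely-at-random demographics (12 missing
#' sex, 46 missing grade, 9 missing both, so listwise deletion retains 89).
#'
#' @param n Number of records.
#' @param class_mix Probabilities (Normal, Borderline, Clinical), summing
#'   to 1.
#' @param sex_mix Probability of `girl`.
#' @param grade_probs Named probability vector over grades 2-12.
#' @param subscale_loading Named per-subscale loading in `[0, 1]` of each
#'   item on the subject's latent severity.
#' @param loading_override Optional named vector (names = item ids) of
#'   per-item loadings overriding the subscale value, e.g. to plant a
#'   zero-loading (uninformative) item.
#' @param class_shifts Latent-severity shifts for the three classes.
#' @param threshold_sets 47 x 3 matrix of strictly increasing latent
#'   cutpoints per item.
#' @param missing_sex,missing_grade,missing_both MCAR missingness counts
#'   (totals; `missing_both` records miss both fields).
#' @param seed Integer seed.
#' @return A list of class `rcads_sim_config`.
#' @export
cohort_config <- function(n = 138L,
                          class_mix = c(0.55, 0.07, 0.38),
                          sex_mix = 0.62,
                          grade_probs = default_grade_probs(),
                          subscale_loading = stats::setNames(rep(0.55, 6), SUBSCALES),
                          loading_override = NULL,
                          class_shifts = c(0, 1.2, 2.0),
                          threshold_sets = default_thresholds(),
                          missing_sex = 12L, missing_grade = 46L,
                          missing_both = 9L,
                          seed = 1L) {
  stopifnot(n >= 0, length(class_mix) == 3L, all(class_mix >= 0),
            abs(sum(class_mix) - 1) < 1e-8,
            sex_mix >= 0, sex_mix <= 1,
            length(grade_probs) == 11L, all(grade_probs >= 0),
            all(SUBSCALES %in% names(subscale_loading)),
            all(subscale_loading >= 0), all(subscale_loading <= 1),
            length(class_shifts) == 3L,
            is.matrix(threshold_sets), nrow(threshold_sets) == 47L,
            ncol(threshold_sets) == 3L,
            all(threshold_sets[, 1] < threshold_sets[, 2]),
            all(threshold_sets[, 2] < threshold_sets[, 3]),
            missing_sex >= 0, missing_grade >= 0,
            missing_both <= min(missing_sex, missing_grade))
  if (missing_sex > n || missing_grade > n || missing_sex + missing_grade - missing_both > n) {
    stop("missingness counts exceed the cohort size")
  }
  grade_probs <- grade_probs / sum(grade_probs)
  structure(list(n = as.integer(n), class_mix = class_mix, sex_mix = sex_mix,
                 grade_probs = grade_probs,
                 subscale_loading = subscale_loading,
                 loading_override = loading_override,
                 class_shifts = class_shifts, threshold_sets = threshold_sets,
                 missing_sex = as.integer(missing_sex),
                 missing_grade = as.integer(missing_grade),
                 missing_both = as.integer(missing_both),
                 seed = as.integer(seed)),
            class = "rcads_sim_config")
}

# Per-item loadings: subscale loading with optional per-item overrides.
item_loadings <- function(cfg, bank) {
  a <- cfg$subscale_loading[bank$items$subscale[order(bank$items$item_id)]]
  a <- stats::setNames(as.numeric(a), 1:47)
  if (!is.null(cfg$loading_override)) {
    ids <- names(cfg$loading_override)
    a[ids] <- as.numeric(cfg$loading_override)
  }
  a
}

# Exact marginal category probabilities implied by the config: the marginal
# latent given class c is N(a * shift_c, 1), so the mixture CDF is closed
# form.
true_item_probs <- function(cfg, bank = rcads_item_bank()) {
  a <- item_loadings(cfg, bank)
  P <- matrix(0, 47, 4, dimnames = list(item_cols(), paste0("p", 0:3)))
  for (i in 1:47) {
    cdf <- rep(0, 3)
    for (c in 1:3) {
      cdf <- cdf + cfg$class_mix[c] *
        stats::pnorm(cfg$threshold_sets[i, ] - a[i] * cfg$class_shifts[c])
    }
    P[i, ] <- diff(c(0, cdf, 1))
  }
  P
}

# Exact within-subscale mean pairwise Spearman correlation implied by the
# config, by quadrature over the latent severity within each class mixture
# component.
true_subscale_spearman <- function(cfg, bank = rcads_item_bank()) {
  a <- item_loadings(cfg, bank)
  grid <- factor_grid()
  out <- stats::setNames(numeric(length(SUBSCALES)), SUBSCALES)
  for (s in SUBSCALES) {
    ids <- bank_items(bank, s)
    conds <- lapply(1:3, function(c) {
      lapply(ids, function(i) {
        cond_cat_probs(cfg$threshold_sets[i, ], a[as.character(i)],
                       cfg$class_shifts[c] + grid$g)
      })
    })
    vals <- c()
    k <- length(ids)
    for (ii in seq_len(k - 1L)) {
      for (jj in seq(ii + 1L, k)) {
        joint <- matrix(0, 4, 4)
        for (c in 1:3) {
          joint <- joint + cfg$class_mix[c] *
            joint_from_cond(conds[[c]][[ii]], conds[[c]][[jj]], grid$w)
        }
        vals <- c(vals, spearman_from_joint(joint))
      }
    }
    out[s] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws each record's class from the configured mix, shifts a standard-normal
#' latent severity by the class shift, generates each item by thresholding
#' `loading * severity + sqrt(1 - loading^2) * noise` at the item's
#' cutpoints, draws sex and grade from their margins, and marks the
#' configured MCAR missingness in sex/grade. Ground truth (exact marginals
#' and correlations, drawn classes) is returned alongside.
#'
#' @param cfg An [cohort_config()].
#' @param bank An [rcads_item_bank()].
#' @return A list with `cohort` (an `rcads_cohort`, provenance
#'   `"synthetic"`) and `truth` (list: `item_probs` 47 x 4 matrix,
#'   `subscale_spearman` named vector, `classes` integer vector 0/1/2 per
#'   record).
#' @examples
#' sim <- simulate_cohort(cohort_config(n = 20, missing_sex = 0,
#'                                      missing_grade = 0, missing_both = 0,
#'                                      seed = 7))
#' nrow(sim$cohort)
#' @export
simulate_cohort <- function(cfg, bank = rcads_item_bank()) {
  stopifnot(inherits(cfg, "rcads_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  a <- item_loadings(cfg, bank)

  classes <- sample(0:2, n, replace = TRUE, prob = cfg$class_mix)
  theta <- cfg$class_shifts[classes + 1L] + stats::rnorm(n)
  X <- matrix(0L, n, 47, dimnames = list(NULL, item_cols()))
  for (i in 1:47) {
    z <- a[i] * theta + sqrt(1 - a[i]^2) * stats::rnorm(n)
    X[, i] <- (z > cfg$threshold_sets[i, 1]) + (z > cfg$threshold_sets[i, 2]) +
      (z > cfg$threshold_sets[i, 3])
  }
  sex <- sample(c("boy", "girl"), n, replace = TRUE,
                prob = c(1 - cfg$sex_mix, cfg$sex_mix))
  grade <- sample(2:12, n, replace = TRUE, prob = cfg$grade_probs)

  # MCAR demographics: `missing_both` records lose both fields, the
  # remainders lose one field each, all disjointly sampled.
  pool <- sample.int(n)
  n_both <- cfg$missing_both
  n_sex_only <- cfg$missing_sex - n_both
  n_grade_only <- cfg$missing_grade - n_both
  idx_both <- pool[seq_len(n_both)]
  idx_sex <- pool[n_both + seq_len(n_sex_only)]
  idx_grade <- pool[n_both + n_sex_only + seq_len(n_grade_only)]
  sex[c(idx_both, idx_sex)] <- NA
  grade[c(idx_both, idx_grade)] <- NA

  df <- data.frame(sex = sex, grade = grade, stringsAsFactors = FALSE)
  df[item_cols()] <- as.data.frame(X)
  list(cohort = new_cohort(df, "synthetic", seed = cfg$seed),
       truth = list(item_probs = true_item_probs(cfg, bank),
                    subscale_spearman = true_subscale_spearman(cfg, bank),
                    classes = classes))
}

#' Build a norm table from a simulated reference population
#'
#' Simulates, per (grade, sex) cell, a reference sample of Normal-regime
#' subjects (latent severity standard normal, no class shift) under the
#' given generator configuration and records the mean and SD of the total
#' raw score. Items do not depend on demographics in the generator, so cells
#' differ only by sampling noise; with `pooled = TRUE` one common reference
#' sample is used for every cell.
#'
#' @param cfg An [cohort_config()]; only its item parameters are used.
#' @param reference_n Records per cell (or pooled total); at least 1000
#'   unless `pooled = TRUE`.
#' @param pooled Use one pooled sample for all cells.
#' @param seed Integer seed (defaults to the config seed).
#' @param bank An [rcads_item_bank()].
#' @return An [norm_table()].
#' @export
build_norms <- function(cfg, reference_n = 2000L, pooled = FALSE,
                        seed = cfg$seed, bank = rcads_item_bank()) {
  stopifnot(inherits(cfg, "rcads_sim_config"), reference_n >= 1L)
  if (!pooled && reference_n < 1000L) {
    stop("reference_n below 1000 per cell; use pooled = TRUE for a pooled fallback")
  }
  set.seed(seed)
  a <- item_loadings(cfg, bank)
  draw_totals <- function(m) {
    theta <- stats::rnorm(m)
    tot <- numeric(m)
    for (i in 1:47) {
      z <- a[i] * theta + sqrt(1 - a[i]^2) * stats::rnorm(m)
      tot <- tot + (z > cfg$threshold_sets[i, 1]) + (z > cfg$threshold_sets[i, 2]) +
        (z > cfg$threshold_sets[i, 3])
    }
    tot
  }
  cells <- expand.grid(grade = 2:12, sex = c("boy", "girl"),
                       stringsAsFactors = FALSE)
  if (pooled) {
    tot <- draw_totals(max(reference_n, 1000L))
    cells$mean <- mean(tot)
    cells$sd <- stats::sd(tot)
  } else {
    ms <- t(vapply(seq_len(nrow(cells)), function(i) {
      tot <- draw_totals(reference_n)
      c(mean(tot), stats::sd(tot))
    }, numeric(2)))
    cells$mean <- ms[, 1]
    cells$sd <- ms[, 2]
  }
  norm_table(cells)
}
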