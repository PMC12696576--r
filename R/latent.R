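# Latent-threshold machinery shared by the synthetic-cohort generator and the
# Gaussian-copula augmentation model.
#
# Both represent an ordinal item as a thresholded Gaussian latent
#   z = a * g + sqrt(1 - a^2) * e,   g, e ~ N(0, 1) independent,
# where g is a factor common to all items of a block (the subject severity in
# the generator, the copula's shared factor in the sampler) and a is the
# loading (sqrt of the latent equicorrelation). Conditional on g the items are
# independent, so joint category probabilities reduce to one-dimensional
# quadrature over g.

# Quadrature grid for the common factor: trapezoid over [-span, span] with
# normal weights, renormalised. 241 nodes give ~1e-9 accuracy on cell
# probabilities, far beyond the 0.01 calibration tolerance.
factor_grid <- function(n = 241L, span = 8) {
  g <- seq(-span, span, length.out = n)
  w <- stats::dnorm(g)
  list(g = g, w = w / sum(w))
}

# Conditional category probabilities P(X = 0..3 | g) for an item with latent
# cutpoints `cuts` (length 3, nondecreasing) and loading `a`, at factor values
# `g` (vector). Returns a length(g) x 4 matrix.
cond_cat_probs <- function(cuts, a, g) {
  s <- sqrt(max(1 - a^2, 1e-12))
  cdf1 <- stats::pnorm((cuts[1] - a * g) / s)
  cdf2 <- stats::pnorm((cuts[2] - a * g) / s)
  cdf3 <- stats::pnorm((cuts[3] - a * g) / s)
  cbind(cdf1, cdf2 - cdf1, cdf3 - cdf2, 1 - cdf3, deparse.level = 0)
}

# Joint 4x4 category table of two conditionally independent items given the
# common factor, integrating the factor out.
joint_from_cond <- function(Pi, Pj, w) t(Pi * w) %*% Pj

# Population Spearman correlation of a discrete pair from its joint table,
# using mid-distribution grades (the large-sample limit of average-rank
# sample Spearman under ties).
spearman_from_joint <- function(joint) {
  p <- rowSums(joint)
  q <- colSums(joint)
  su <- 1 - sum(p^3)
  sv <- 1 - sum(q^3)
  if (su <= .Machine$double.eps || sv <= .Machine$double.eps) return(NA_real_)
  u <- cumsum(p) - p / 2
  v <- cumsum(q) - q / 2
  (sum(joint * outer(u, v)) - 0.25) * 12 / sqrt(su * sv)
}

# Latent cutpoints reproducing marginal category probabilities `p` under a
# standard normal latent. qnorm maps cumulative 0 and 1 to -Inf/Inf, which
# the conditional-probability code handles.
cuts_from_probs <- function(p) {
  stopifnot(length(p) == 4L, abs(sum(p) - 1) < 1e-8, all(p >= 0))
  stats::qnorm(pmin(cumsum(p)[1:3], 1))
}

#' Mean pairwise Spearman correlation induced by a latent equicorrelation
#'
#' For a block of ordinal items with given marginal category probabilities,
#' sampled by discretising an equicorrelated Gaussian vector, computes the
#' population mean pairwise Spearman correlation of the discrete responses.
#' Discretisation attenuates correlation, so this is strictly below the
#' latent value; [calibrate_latent_rho()] inverts the map.
#'
#' @param latent_rho Gaussian equicorrelation in `[0, 1)`.
#' @param probs_list List of length-4 probability vectors, one per item
#'   (categories 0-3, each summing to 1).
#' @param grid Optional quadrature grid from `factor_grid()`.
#' @return Mean over all item pairs of the induced Spearman correlation;
#'   pairs involving a constant item are excluded.
#' @export
induced_spearman <- function(latent_rho, probs_list, grid = NULL) {
  stopifnot(latent_rho >= 0, latent_rho < 1, length(probs_list) >= 2L)
  grid <- grid %||% factor_grid()
  a <- sqrt(latent_rho)
  conds <- lapply(probs_list, function(p) cond_cat_probs(cuts_from_probs(p), a, grid$g))
  k <- length(conds)
  vals <- c()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      vals <- c(vals, spearman_from_joint(joint_from_cond(conds[[i]], conds[[j]], grid$w)))
    }
  }
  mean(vals, na.rm = TRUE)
}

#' Calibrate the latent Gaussian correlation to a target Spearman correlation
#'
#' Bisection on the latent equicorrelation so that the post-discretisation
#' mean pairwise Spearman correlation (computed by deterministic
#' common-factor quadrature) matches `target`. Targets at or above the
#' attainable maximum (latent correlation -> 1) are clamped with a warning.
#'
#' @param target Target mean pairwise Spearman correlation in `[0, 1)`.
#' @param probs_list Per-item marginal probabilities, as in
#'   [induced_spearman()].
#' @param tol Tolerance on the induced correlation (default 0.005, inside the
#'   0.01 the model promises).
#' @param max_iter Maximum bisection steps (default 40).
#' @return The calibrated latent equicorrelation.
#' @export
calibrate_latent_rho <- function(target, probs_list, tol = 0.005, max_iter = 40L) {
  stopifnot(is.numeric(target), length(target) == 1L)
  if (target < 0) {
    warning("negative target correlation clamped to 0")
    target <- 0
  }
  if (target == 0) return(0)
  grid <- factor_grid()
  hi <- 0.9995
  f_hi <- induced_spearman(hi, probs_list, grid)
  if (is.na(f_hi) || target >= f_hi) {
    warning(sprintf(
      "target correlation %.3f at or above attainable maximum %.3f; clamping latent correlation to %.4f",
      target, if (is.na(f_hi)) NA_real_ else f_hi, hi))
    return(hi)
  }
  lo <- 0
  f_mid <- NA_real_
  mid <- NA_real_
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- induced_spearman(mid, probs_list, grid)
    if (abs(f_mid - target) <= tol) return(mid)
    if (f_mid < target) lo <- mid else hi <- mid
  }
  if (abs(f_mid - target) <= 0.01) return(mid)
  stop(sprintf(
    "latent correlation calibration did not converge in %d steps (bracket [%.5f, %.5f], induced %.4f, target %.4f)",
    max_iter, lo, hi, f_mid, target))
}
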