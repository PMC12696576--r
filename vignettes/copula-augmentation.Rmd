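---
title: "Copula augmentation and screening models for RCADS-47 cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copula augmentation and screening models for RCADS-47 cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcadscreen)
```

## The problem

The RCADS-47 is a 47-item self-report questionnaire for child anxiety and
depression: four ordered response levels per item (0 = Never to 3 = Always)
and six internalizing subscales (MDD, GAD, OCD, PD, SAD, SP). Screening
classifies a child from the total internalizing T-score into Normal
(T < 65), Borderline (65 ≤ T < 70) or Clinical (T ≥ 70). Clinic cohorts
are small — listwise deletion of incomplete assessments can leave fewer
than 90 records — and the Borderline class is rare (a few percent), so a
multi-class classifier trained directly on such a cohort generalises
poorly. `rcadscreen` implements the full workflow for this setting:
scoring, reliability analysis, consensus feature elimination,
Gaussian-copula augmentation of the item responses, SMOTE balancing, and
grid-searched multi-class model development.

This vignette documents the models, the tunable parameters, and the design
choices taken where the procedure was genuinely open.

## Scoring and labels

Raw totals are sums of the 47 levels (0–141). T-scores are affine,
`T = 50 + 10 (raw − μ)/σ`, with `(μ, σ)` looked up per (grade, sex) cell
of a norm table. Official published norms are not shipped: scoring against
them is not the package's contribution, and tests must not depend on
values the package cannot verify. Instead, `build_norms()` constructs a
table from a large simulated reference population under the Normal-class
regime of the generator (default 2000 records per cell; cells are
statistically identical in the generator, so `pooled = TRUE` is available
for a common reference). Any user-supplied table with positive SDs
covering grades 2–12 × sex is accepted, and grade bands are expressed by
repeating rows.

The Borderline band "between 65 and 69" is implemented as the half-open
interval `65 ≤ T < 70`, so arbitrary real T-scores (e.g. 69.4) are covered
and the three labels partition the line.

Classification uses the total internalizing score only; subscale T-scores
are out of scope.

## The synthetic-cohort generator

Every downstream stage is tested against cohorts with known ground truth.
The generator is a one-factor latent-threshold model per subject:

* a class `c` is drawn from the configured mix (default 55% Normal, 7%
  Borderline, 38% Clinical);
* the subject's severity is `θ = δ_c + ε`, `ε ~ N(0,1)`, with class shifts
  `δ = (0, 1.2, 2.0)` — a configurable default chosen so the three classes
  overlap realistically on the raw-score scale rather than separating
  cleanly;
* item `i` responds with the number of its cutpoints below
  `a_i θ + √(1−a_i²) e_i`, `e_i ~ N(0,1)`; the loading `a_i` defaults to
  0.55 for all subscales, which yields within-subscale inter-item Spearman
  correlations around 0.3–0.4 and an overall inter-item range of roughly
  0.1–0.6, the weak-to-moderate band typical of the instrument;
* cutpoints default to `(0.2, 1.0, 1.8)` plus a deterministic per-item
  offset cycle (−0.3 … 0.3), so marginals vary across items but carry no
  hidden randomness;
* sex (38/62 boy/girl) and grades 2–12 (clinic-like margin) are drawn
  independently of the items;
* missingness is MCAR and restricted to sex/grade (default 12 missing sex,
  46 missing grade, 9 both, so listwise deletion keeps 89 of 138) —
  matching the setting where only demographics are incomplete.

Ground truth is exact, not estimated: marginal category probabilities have
a closed form (the latent given class is Gaussian), and within-subscale
population Spearman correlations are computed by the same common-factor
quadrature used for calibration (below). The drawn classes are returned
alongside the labels computed by scoring, so label agreement itself is
observable.

What the generator does **not** emulate: informative missingness, response
styles (acquiescence, extreme responding), inter-subscale dependence beyond
the single severity factor, and item-level cultural effects. Passing tests
therefore demonstrate correctness of the machinery under a plausible
one-factor world, not fidelity to any particular clinical population.

## Reliability

`cronbach_alpha()` implements the variance form
`α = k/(k−1)(1 − Σ s²ᵢ / s²_total)` with n−1 denominators; the test suite
checks it against the independent covariance-matrix form
`k/(k−1)(1 − tr(C)/ΣC)` to 10⁻¹². Alpha is undefined (an error) when the
total has zero variance. Inter-item summaries use Spearman correlations
with average-rank ties — the coefficient consistent with the ordinal
treatment used everywhere else; pairs involving a constant item are
excluded with a warning count rather than propagated as NA.

## Consensus feature elimination

Three screens run per item against the class label: chi-square independence
(no continuity correction; cells with expected counts below 5 are counted
and warned about, not silently re-tested — sparse 4×3 tables are inevitable
at n ≈ 89), Spearman correlation (large-sample t approximation), and
RF-RFE. The RF-RFE wrapper removes one feature per step by impurity
importance and records mean stratified 5-fold CV accuracy at each size; the
selected size maximises CV accuracy with ties resolved toward the smaller
set, so the feature count is determined by the data. Defaults (100 trees,
one elimination per step, accuracy criterion, fixed seed) are conservative
and configurable.

An item is eliminated only on unanimity: chi-square p > α, Spearman
p > α, and exclusion by RF-RFE, at α = 0.05 (configurable). With a planted
zero-loading item at n = 356 the unique elimination is recovered in well
over 80% of seeded runs.

## The copula augmentation model

`fit_augmentation()` estimates, from a complete cohort:

* per-item multinomial probabilities `(p₀, p₁, p₂, p₃)` — empirical
  frequencies;
* demographic margins for sex and grade (items and demographics are
  generated independently of each other, reflecting their weak observed
  association);
* a per-subscale target correlation: the mean pairwise inter-item Spearman
  correlation within the subscale, clamped to [0, 0.99]. The phrase
  "average correlation between the questions and the target evaluation of
  each subscale" admits an item-to-subscale-total reading; that variant is
  available as `rho_mode = "item_total"` (squared to an exchangeable
  pairwise target), but the pairwise reading is the default because it is
  the quantity an exchangeable generator can directly reproduce.

Sampling is per subscale with independent blocks (inter-subscale
correlation is deliberately not modelled): draw an equicorrelated Gaussian
vector via the shared-factor construction `z_j = √ρ G + √(1−ρ) e_j`, map
`u_j = Φ(z_j)`, and return the smallest level whose cumulative probability
reaches `u_j`. Marginals are therefore preserved exactly in expectation.

### Latent-correlation calibration

Discretising correlated Gaussians attenuates correlation: using the target
Spearman directly as the latent `ρ` systematically undershoots. The
calibration inverts the attenuation map. For a pair of items with cutpoints
`c` and `d` and latent equicorrelation `ρ`, the items are conditionally
independent given the shared factor `G`, so the joint 4×4 cell table is a
one-dimensional integral of products of conditional normal CDFs —
evaluated by a 241-node trapezoid rule over `G ∈ [−8, 8]` (cell accuracy
far below the stated 0.01 tolerance, and fully deterministic). The
population Spearman of a discrete pair follows from mid-distribution
grades: with joint `p_ab`, marginals `p`, `q`,
`ρ_S = 12 (Σ p_ab u_a v_b − ¼) / √((1−Σp³)(1−Σq³))`,
`u_a = F(a−) + p_a/2`. `calibrate_latent_rho()` bisects the latent `ρ`
(monotone in the induced value) until the induced mean pairwise Spearman is
within 0.005 of target, erroring with the bracket after 40 steps, and
clamping with a warning when the target exceeds the attainable maximum.
The test suite cross-checks the whole map against a 10⁶-sample Monte-Carlo
oracle.

Synthetic labels are **computed**, not sampled: each generated record is
scored and classified against the norm table, so labels remain a
deterministic function of the features, exactly as for real records.

### Fidelity

`fidelity()` compares original and synthetic cohorts per item with
two-sided Mann–Whitney tests (tie-corrected normal approximation) and
total-variation distances, and per subscale with the achieved-vs-target
mean correlation gap. Under matched generators at ratio 1:4 the number of
items rejected at the 5% level stays at or below 5 of 47 in ≥ 90% of
seeded runs, while a 0.3-mass shift planted in one item is rejected at
p < 0.01.

## Model development

SMOTE balances the three classes to the majority count by uniform
interpolation toward one of k = 5 nearest same-class neighbours;
interpolated values stay continuous by default (`round_levels = TRUE`
restores ordinal levels). The evaluation order applies SMOTE **before**
the stratified 80/20 split (test size `⌈0.2 n⌉`), which reproduces the
modelled workflow and its shapes — class counts (49, 6, 34) balance to 147
and split 117/30 — but leaks interpolated information into the test set;
the pipeline emits a prominent warning and offers
`smote_order = "split_then_balance"` as the methodologically clean
alternative.

Six families are tuned by exhaustive grid search with stratified 5-fold CV
(selection by mean fold accuracy, ties to the first candidate in grid
order, refit on the full training set): random forests (trees 50/100/200,
depth unlimited/10/20/30, minimum node size to split 2/5/10, minimum leaf
1/2/4 — via `ranger`), SVM (C 0.1/1/10/100, linear/RBF, gamma scale
`1/(p·Var X)` or auto `1/p` — via `e1071`), logistic regression (C
0.01/…/100, penalty l1/l2, mapped to `glmnet` multinomial with
`λ = 1/(C·n)`; the l1/l2 grid is the only reading consistent with the
reported best setting "penalty = l1"), decision trees (depth/split/leaf as
RF plus gini/entropy — `rpart` with `cp = 0`), Gaussian naive Bayes (no
grid), and k-NN (3/5/7/9 neighbours, uniform/distance weights,
Euclidean/Manhattan — implemented in-package because no installed engine
offers distance weighting with the Manhattan metric).

Reports give per-class precision/recall/F1 (zero convention with a warning
for never-predicted classes), accuracy, macro and support-weighted
averages, the 3×3 confusion matrix, CV fold scores and the selected
hyperparameters. `compare_models()` runs the paired two-sided t-test on
fold accuracies, returning p = 1 with a note for all-zero differences and
an error for nonzero constant differences (zero-variance pathologies).
`external_validate()` scores a frozen model on a new cohort, reporting the
full confusion matrix — with a rare Borderline class, its row is where
generalisation typically degrades.

## Numerical and testing choices

* All randomness is seeded; pipeline stages derive independent seeds from
  one master seed by stage-name hashing, and manifests record MD5 hashes
  of every output so reruns are verifiable.
* Problem sizes in the test suite are chosen to keep the default run in
  the minutes range while leaving comfortable statistical margins:
  independence and marginal-preservation checks at n = 10⁴–10⁵, marginal
  recovery at n = 1780 (ratio 1:20 of 89), calibration oracles at 10⁶,
  consensus recovery over 50 seeded runs at n = 356, and end-to-end
  hybrid-training over 20 seeds at the cohort's native n = 89.
* The end-to-end guarantee is deliberately modest: a default random forest
  trained on the 1:4 hybrid reaches macro-F1 ≥ 0.6 on a fresh cohort from
  the same generator in ≥ 18 of 20 seeds. The Borderline band is narrow,
  so its F1 dominates the macro average's variance; 0.6 is a property of
  the machinery, not a clinical performance claim.

## Known limitations

Independent subscale blocks ignore the (substantial) inter-subscale
correlation a single severity factor induces in real data; hybrid
classifiers partly recover it from the original records, but
augmentation-only analyses should not rely on cross-subscale structure.
Demographics are independent of items in both generator and augmentation
model. The balance-then-split default exists to mirror the modelled
workflow and overstates test performance; use the split-first mode for
honest estimates. Norm tables built from the simulated reference are
internally consistent but are not the instrument's published norms, so
absolute T-scores are only meaningful relative to the chosen reference.
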