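---
title: "Two-stage feature selection for small mixed-type clinical cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage feature selection for small mixed-type clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical cohorts of cancer survivors are typically small (on the order of
100 records), mixed-type (continuous biomarkers, binary treatment flags,
categorical demographics), imbalanced (the adverse behavioral outcome is
the minority class), and wide relative to their depth (50 or more
candidate predictors). Classical feature-selection families struggle
here: filter methods ignore redundancy between predictors, wrapper
methods overfit, and penalized linear models miss nonlinear and
interaction effects. `ddnselect` implements a hybrid two-stage selector
built for this regime, embedded in a full preprocessing and evaluation
pipeline, together with a synthetic-cohort generator so every stage can
be exercised and validated without access to any private clinical data.

## Stage 1: a multimetric majority-voting filter

For a binary outcome $Y$ and each candidate feature $X$, four relevance
scores are computed:

* **MIC**, the maximal information coefficient, a $[0,1]$ measure of any
  linear or nonlinear association, estimated with the
  characteristic-matrix approximation (grids bounded by $B(n) = n^{0.6}$,
  clump factor 15). One axis is equipartitioned and the other optimized
  by dynamic programming over clumps; both orientations are scanned, so
  the estimate is exactly symmetric. The estimator depends on the data
  only through ranks, making it invariant under monotone transforms.
* **1 − GI**, the complement of the split-weighted Gini impurity of $Y$
  under the partition induced by $X$ (binary features partition by
  value; continuous features use the single best decision-stump
  threshold over midpoints of sorted unique values). The complement is
  used so that, like the other metrics, higher means more relevant.
* **IG**, the information gain $H(Y) - H(Y \mid X)$ in bits (log base 2,
  so IG of a binary outcome is bounded by 1). Continuous features are
  discretized by equal-frequency binning with $\min(10, \#\text{unique})$
  bins — a deterministic choice that is robust at $n \approx 100$.
* **CS**, the absolute correlation: Pearson for continuous pairs,
  point-biserial for continuous–binary, and the $\phi$ coefficient for
  binary pairs. All three are Pearson correlations of suitably coded
  vectors, and the absolute value keeps the score in $[0,1]$.

The top $N$ features per metric (default $N = 15$, the size domain
experts asked for in the motivating study) are collected; features
selected by at least 3 of the 4 metrics form the high-confidence set
F_3M+, features selected by exactly 2 form the candidate set F_2M, and
features selected by a single metric are discarded. Ties in scores are
broken by column order so results are deterministic on small cohorts
where ties do occur. Each pooled feature also gets an average rank (mean
1-based position over the lists that contain it; a variant scoring
absences at $N+1$ is available via `rank_over = "all4"`).

Redundant pairs are then pruned: for every pool pair, $1-\text{MIC}$ and
$1-\text{CS}$ are computed, and a pair with both below 0.05 is
redundant. Pairs are processed most-redundant first; the member with
fewer votes is removed, ties go to the worse average rank, and a
residual tie removes the later column with a warning. If the pool is too
small (before pruning: below `min_pool`, default $N$; after pruning:
below $N$), the per-metric depth is increased by 5 and the selection
re-run, at most 3 times.

## Stage 2: a deep dropout network as the wrapper

When F_3M+ alone does not reach $N$ features, subsets of F_2M (all
non-empty subsets of size at most $N - |F_{3M+}|$, ordered by size and
then lexicographically) are appended to F_3M+ and scored by the mean
stratified 5-fold cross-validated F1 of a small feed-forward network:
2 hidden ReLU layers of width $\lceil (I+1)/2 \rceil$ for $I$ inputs,
dropout after each hidden layer, one sigmoid output unit, binary
cross-entropy loss, Adam at learning rate 0.001, mini-batches of 16.
The dropout rate is tuned once by grid search on the baseline F_3M+ set
(default grid 0, 0.1, ..., 0.5; ties prefer the smaller rate) and reused
for every candidate subset, so subset comparisons are paired: the same
folds, the same initialization stream, the same dropout. The final list
is the candidate with the highest mean CV F1 if it strictly beats the
baseline, otherwise F_3M+ alone.

Numerical choices worth knowing about:

* Predictions are thresholded at 0.5; a held-out fold with no positive
  instances contributes F1 = 0 with a warning.
* At the very small hidden widths the sizing rule produces for short
  feature lists (width 1–2), an unlucky initialization can leave an
  entire ReLU layer inactive for every input — a dead network whose
  gradients are all zero. Hidden biases are therefore initialized at
  0.1, and a fit that fails to beat the majority-class training accuracy
  is re-initialized (deterministically, from the continuing RNG stream)
  up to 3 times.
* All training randomness flows through R's RNG, so a single seed makes
  selection bitwise reproducible.

## The surrounding pipeline

`run_pipeline()` chains the framework stages in fixed order: group-wise
mean/mode imputation (groups defined by schema key columns such as
cancer type, age range and sex, falling back to global statistics),
one-hot encoding (2-level categoricals collapse to one 0/1 column),
normality-guided normalization, SMOTE-NC class balancing, a stratified
train/test split (default fraction 0.696, reproducing a 71/31 split of
102 records), the two selection stages, a clinical overlay that appends
mandated features (for example sex, current age, age at diagnosis), and
evaluation of the final list with logistic regression, Gaussian naive
Bayes and 5-nearest-neighbors, reporting precision, recall and F1 of the
positive class with cross-classifier means and variances.

Normality is decided by a 2-of-3 vote among Shapiro–Wilk, one-sample
Kolmogorov–Smirnov against a Gaussian with the sample moments, and the
D'Agostino–Pearson omnibus $K^2$ test, each at $\alpha = 0.05$ (the
reference distribution for the KS test and the per-test level are
configuration choices; the omnibus test is implemented from the standard
skewness/kurtosis $z$ transformations because no installed package
provides it, and matches an independent reference implementation to ten
decimals). Features judged normal are z-scored; all others are min-max
scaled to $[0,1]$; 0/1 indicators are left untouched, because min-max is
the identity on them and z-scoring indicators would break SMOTE-NC's
nominal handling.

SMOTE-NC follows the mixed-type oversampling recipe: distances between
minority records are Euclidean over continuous features plus
$\text{med}^2$ once per differing nominal feature, where med is the
median of minority-class continuous standard deviations; synthetic
records interpolate continuous values at a uniform random fraction
toward one of the $k = 5$ nearest minority neighbors and take nominal
values by majority vote among those neighbors. Balancing precedes the
split by default, mirroring the framework's module order; this leaks
synthetic points (interpolants of training records) into the test set,
so a `balance_after_split` flag moves balancing to the training side
only for users who prefer correctness over fidelity. How a secondary
(for example sex) balancing pass should interact with outcome balancing
is not well defined; it is implemented as an optional second pass
(`balance_column`), disabled by default.

Baseline selectors from the four classical families (CFS/IG/MRMR
filters, SVM-scored forward/backward/stepwise wrappers, Lasso/Ridge/
ElasticNet embedded selectors, and their filter-then-wrapper hybrids)
are provided as comparators behind light behavioral contracts; they
delegate to `glmnet` and `e1071` where a standard implementation
exists.

## The synthetic cohort generator

`generate_cohort()` draws seeded cohorts with the structure the method
assumes: by default 102 records and 50 mixed features (35 continuous
with mixed Gaussian/log-normal marginals, 15 Bernoulli), a binary
outcome of prevalence 0.25 drawn from a logistic model whose intercept
is solved numerically, 5 planted predictors with log-odds effects
1.5, 1.25 and 1.0 (linear), 1.0 (threshold at 0) and 0.75 (product
interaction with the strongest linear feature), 2 redundant columns
(a near-copy and an affine transform of noise features, noise SD at or
below 0.01), and 5% MCAR missingness. The effect types deliberately mix
strengths and shapes so that strong linear effects are recovered
essentially always while the nonlinear effects sit near the filter's
detection boundary — recovery experiments stay sensitive rather than
saturated. The generator does not emulate the real cohort's covariance
structure, instrument score distributions, or treatment semantics, so
passing recovery tests demonstrate the algorithmic behavior of the
selector, not clinical validity on any real population.

Problem sizes used by the test-suite experiments were chosen at desk
scale: recovery and redundancy experiments run 20–50 seeds at
$n \approx 100$ with 100–200 training epochs, and the acceptance script
reports the seed counts it used alongside each quantity.

## Radial feature charts

For reporting, each selected feature receives a unified metric value:
the mean of the scores of exactly those metrics whose top-$N$ list
selected it. The radial chart draws one equal-angle slice per feature
with radial extent and red saturation proportional to the unified value
normalized by the chart maximum (a per-chart normalization; the
alternative — normalizing across all outcomes of a study — is equally
defensible but less readable when outcomes differ in overall signal).
Features added by the clinical overlay have no selecting metrics; they
are drawn as hollow dashed slices at a minimal radius so their mandated
inclusion is not misread as measured irrelevance.

## Known limitations

* With a few hundred to a few thousand candidate subsets and only
  ~100 balanced training records, the cross-validated F1 differences
  between candidates are often smaller than CV noise; the stage-2
  arg-max then behaves like a draw among near-ties, and weak planted
  effects (log-odds around 1.0 at this sample size) are pulled into the
  final list unreliably. This is a property of wrapper search at small
  $n$, and it is compounded by pre-split balancing. The package reports
  the full per-subset log so users can inspect how decisive the winner
  was.
* Width-1 networks (single-feature baselines) remain occasionally hard
  to optimize even with re-initialization.
* Imputation is group mean/mode only; longitudinal records, non-binary
  outcomes and survival endpoints are out of scope.
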