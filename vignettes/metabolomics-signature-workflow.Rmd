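---
title: "A stability-selected metabolomic signature workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stability-selected metabolomic signature workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`metabosig` implements a complete two-group discrimination workflow for
untargeted LC-MS metabolomics feature tables: reliability filtering against
QC and blank injections, probabilistic quotient normalization (PQN), PCA
outlier gating, D-optimal "onion" balancing of unequal groups, PLS2C
classification with VIP-based stability selection, permutation-based
significance, and a univariate fold-change / Mann-Whitney / Storey-q screen.
This vignette documents the model, every default, and the conventions that
matter for reproducing numbers exactly.

## Data model

A `feature_table` holds a samples-by-features intensity matrix (`NA` =
not detected), a role per row (`Study`, `QC`, `Blank`), and a class label
per study row. Features are `Rt_mass` variables — retention time and m/z,
e.g. `1.23_180.0634`. QC rows are pooled aliquots of all study samples and
are stable by construction; blanks are mobile-phase-only injections.

```{r, eval = FALSE}
library(metabosig)
sim <- generate_cohort(sim_config(seed = 1))
sim$table
```

## Preprocessing cascade

`preprocess()` applies five stages in a fixed order and returns a
telescoping filter report (each row counts the features surviving that
stage):

1. **Missing-in-QC filter** — a feature undetected in *any* QC injection
   is unreliable and is dropped.
2. **Blank-ratio filter** — drop features whose 95th percentile across
   blanks exceeds `blank_ratio_threshold` (default **0.20**) times their
   5th percentile across QCs. Percentiles use the type-7 quantile
   definition (R's default). The 95-vs-5 pairing is deliberately
   conservative: a feature is kept only when almost all blank signal sits
   well below almost all QC signal.
3. **QC coefficient-of-variation filter** at `max_qc_cv` (default
   **0.20**), using the sample (n − 1) standard deviation. Applied both
   before and after normalization: PQN can either fix or unmask poor
   repeatability.
4. **Imputation** — remaining `NA`s are left-censored (below the detection
   limit), so each is drawn uniformly on (0, minimum observed value of
   that feature). Seeded; bit-reproducible via `withr::with_seed()`.
5. **PQN** — each sample is divided by the median, over features, of its
   quotients to a reference spectrum. The reference is the feature-wise
   median of the **QC rows** (default): the pooled sample is undiluted by
   construction, so quotients estimate the per-sample dilution factor
   directly. `reference = "study"` falls back to the study median.

Modelling then uses `log_center()`: natural log followed by mean-centering.
Features are **not** scaled to unit variance; intensities already live on a
common scale after normalization and the log transform, and centering-only
preserves the natural weighting of the measured variances. The consequences
of this choice for variable selection are discussed at the end.

## PCA quality control

`fit_pca()` is a thin SVD with a deterministic sign convention (the
largest-magnitude element of each loading is made positive). The component
count is the smallest number reaching `pca_variance_target = 0.60`
cumulative explained variance. `outlier_test()` flags samples by:

- **Hotelling T²** on the scores, with limit
  `A (n − 1) / (n − A) · F(1 − α; A, n − A)`;
- **Q (squared prediction error)** on the residuals, with the
  Jackson–Mudholkar limit computed from the residual eigenvalues.

Both at `alpha = 0.05`. Under a correctly specified model null the flag
rates sit near the nominal 5% (verified in the test suite at n = 2000).

## Onion D-optimal balancing

When groups are unequal, `run_comparison()` selects a representative
subset of the majority class of size `ceiling(1.2 × minority)` (override
with `design_k`). Candidates are described by their standardized PCA
scores plus standardized Q residual, so both the modelled and unmodelled
variation count. `onion_select()`:

1. ranks candidates by distance from the centroid and cuts them into
   `n_layers = 3` concentric shells of (near-)equal size — enough to
   separate core, mantle and rim without starving any layer;
2. apportions the budget across layers by largest remainder;
3. within each layer runs a Fedorov exchange maximizing `det(X'X)` of the
   design matrix `[1 | coords]`, with 20 random restarts.

This yields a spread that covers the full intensity cloud instead of the
dense center only. On small instances the exchange recovers the exhaustive
optimum (tested against all 10-choose-4 subsets).

## PLS2C, VIP and stability selection

`fit_pls2()` is NIPALS PLS2 regression on a two-column dummy-coded class
response with deflation of both blocks; `classify()` predicts the class
with the larger predicted dummy value (ties resolve to the lower label
index). At full rank the fit equals ordinary least squares.

Variable importance in projection for feature *j*:

`VIP_j = sqrt( p · Σ_a SS_a w_ja² / Σ_a SS_a )`, with
`SS_a = |t_a|² |q_a|²`, so that `Σ_j VIP_j² = p` and the mean square is 1.
Features with VIP < 1 carry less than average influence.

The component count `A` is chosen by `select_components()`: repeated
stratified cross-validation (5-fold, `cv_repeats` repeats; predictions are
pooled within each repeat, MCC computed per repeat and averaged) yields an
MCCcv profile over `A`, and the **first local maximum** is taken — the
smallest `A` whose MCCcv is not improved by adding a component.

`stability_selection()` (defaults `n_sub = 200`, `frac = 0.8`,
`vip_threshold = 1`, relevance cut-off `0.5`):

- draws stratified 80% subsamples;
- in each, iteratively removes VIP < 1 features, scoring every iteration
  by a light internal CV (5-fold, 1 repeat) and keeping the iteration with
  the best MCCcv;
- records, per feature, the fraction of sub-models whose best set
  contains it (the *selection frequency*);
- predicts each sample from the sub-models in which it was out-of-bag and
  reports the majority-vote **MCCoob**;
- calls features with frequency ≥ 0.5 *relevant*.

Model significance uses `permutation_test()` with the add-one convention
`p = (1 + #{perm ≥ observed}) / (n_perm + 1)`, the observed statistic being
the repeated-CV MCC. A random forest (`randomForest`, internal out-of-bag
votes) is run through the same MCC machinery as an orthogonal check.

## Univariate screen

`volcano_table()` works on the normalized, **un-logged** intensities of
the samples actually modelled: fold change is the ratio of group medians,
p-values come from the Mann-Whitney test (exact when n ≤ 20 without ties),
and multiplicity is handled by Storey q-values. π0 is estimated with the
λ-smoother (natural spline over λ = 0.05, …, 0.95 evaluated at 0.95,
clipped to (0, 1]); with π0 = 1 the q-values reduce exactly to
Benjamini–Hochberg. Default flags: |log2 FC| ≥ 1 and p < 0.05.

## Synthetic cohorts

`generate_cohort()` provides ground-truthed data for validation:
log-normal intensities (`meanlog ~ U(log 10³, log 10⁶)`,
`sdlog ~ U(0.2, 0.6)` — spanning tight to moderately variable features), a
planted shift of `effect_size` (default 2) within-feature SDs in class B
for `n_discriminant` features, per-sample dilution `U(0.5, 2)` removed by
PQN, QCs as the per-feature mean of the undiluted study samples with 10%
CV noise, blanks at 2% of the median for a contaminated 5% feature subset,
and intensity-dependent missingness (values below the study 10th
percentile censored with probability `missing_rate`). All randomness flows
through seeded child streams, so every run is bit-reproducible.

Default problem size — 30 + 30 samples, 500 features, 10 planted, 8 QCs,
4 blanks — keeps a full `run_comparison()` in the minutes range.

## A known limitation

Because modelling uses centering without unit-variance scaling, PLS
weights — and therefore VIP and the selection frequencies — scale with a
feature's variance on the log scale. Planted features with small `sdlog`
can be eliminated early in some realizations even though their
*standardized* effect size equals that of high-variance features; across
seeded replicates the planted-feature selection frequency correlates
strongly (r ≈ 0.8–0.9) with `sdlog`. This is a property of the method as
specified, not of the implementation; the test suite documents it by
asserting the recovery rate honestly. Unit-variance scaling would remove
the bias at the cost of amplifying noise features and departing from the
stated preprocessing.

## Reproducibility conventions

- every stochastic step takes a `seed` and uses `withr::with_seed()`;
- independent sub-streams come from `child_seeds()`, so adding a stage
  never perturbs another stage's draws;
- MCC returns 0 when its denominator vanishes;
- quantiles are type 7, standard deviations use n − 1 throughout.
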