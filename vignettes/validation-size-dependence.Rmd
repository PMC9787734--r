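---
title: "Sample-size dependence of regression validation metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-size dependence of regression validation metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizeval)
```

## The problem

A regression model is validated along three aspects: goodness of fit
(training-set $R^2$ and RMSE), robustness (cross-validated $Q^2_{LOO}$,
$Q^2_{LMO}$, $RMSE_{LOO}$), and predictivity (external $Q^2_{F2}$,
$RMSE_{test}$). These numbers are not fixed properties of a model family on
a dataset: every one of them is a function of the training-set size, and
they move in different directions. `sizeval` provides the machinery to map
those curves, the randomization nulls that calibrate them, and the rank
correlations that reveal which metrics are redundant.

## Metric definitions and conventions

All intensive metrics are ratios of sums of squares of one response
vector; all extensive metrics are in response units.

- $R^2 = 1 - RSS/TSS$ with $TSS$ about the training mean. MSS is computed
  about the mean of the *fitted* values; the decomposition $RSS + MSS =
  TSS$ — and with it $0 \le R^2 \le 1$ — is asserted only for OLS fits
  with an intercept, where it is an algebraic identity. For PLS, networks
  and SVR, $R^2$ may be negative and only $R^2 \le 1$ holds.
- $RMSE = \sqrt{RSS/n}$ with no degrees-of-freedom correction, matching
  the use of unadjusted $R^2$: the metrics describe reproduction of the
  data, not an unbiased variance estimate.
- $Q^2_{LOO} = 1 - PRESS/TSS$ and $Q^2_{LMO}$ use the **full
  training-set** mean in TSS, not per-fold means. A per-fold variant
  exists in the literature; the full-mean reading keeps LOO and LMO on the
  same denominator, which is what makes them comparable on a common axis.
- $Q^2_{F2}$ uses the **test-set** mean in its denominator, so a model
  predicting the test mean scores exactly 0, and negative values mean
  "worse than the mean".
- Multi-response (PLS2) fits compute every metric per response; reported
  scalars are per-response averages, and the per-response values remain
  available (`q2_per_response` attribute, `goodness_of_fit()` per column).

For OLS the leave-one-out residual of case $i$ is $e_i/(1-h_{ii})$,
giving PRESS from a single fit. `press_hat_matrix()` refuses saturated
designs ($h_{ii} \to 1$) and rank-deficient ones rather than returning
meaningless numbers; equality with explicit refitting is enforced in the
test suite at 1e-8 relative tolerance, the scale of double-precision
round-off in these quadratic forms.

## Model adapters

The scientific contribution of the package is the validation machinery,
not the optimizers, so fitting is delegated to mature implementations
behind a uniform `model_spec()`/`fit_model()` surface:

- **mlr** — QR-based ordinary least squares on all predictors with a free
  intercept; `p_params = p`.
- **pls2** — a NIPALS implementation written here (no suitable
  lightweight two-block PLS is guaranteed at runtime; the test suite
  cross-checks predictions against `mixOmics::pls` when that package is
  present, and against the OLS limit at full latent rank). Latent pairs
  maximize covariance on residual matrices; optional autoscaling of both
  blocks (`standardize_x`, `standardize_y`, default on) matters whenever
  variable scales differ. The latent-variable count `n_latent` is a
  *required* user choice: no automatic selector is offered because the
  internal and external validation curves it trades off do not in general
  share an optimum. The package exposes the per-`n_latent` curves; the
  user picks the compromise.
- **ann** — `nnet::nnet` with linear output: one hidden layer of logistic
  units trained by BFGS. This is deliberately the narrowest credible
  network: alternative activations (tanh, relu) and stochastic optimizers
  add hyperparameter axes without changing the validation phenomena under
  study, and `nnet` is the single-hidden-layer tool of record in R. The
  default hidden-layer size follows the capacity rule implemented in
  `hidden_units_for()`: as many weights as there are cases at the
  smallest sweep size, i.e. $H (p+2) + 1 \approx n$. Fits are stochastic
  through the starting weights and reproducible given the R RNG;
  non-convergence is flagged (`converged`), never an error.
- **svr** — `e1071::svm` epsilon-regression with an RBF kernel. Defaults
  `gamma = 1/p`, `epsilon = 0.1`, `cost = 1` follow libsvm conventions.
  The support-vector count and fraction are first-class diagnostics: a
  fraction near 1 means the model memorizes the sample, which is exactly
  the regime in which its goodness of fit stops meaning anything. When
  the epsilon tube is wider than the response spread libsvm produces an
  empty model; the adapter returns the correct limit (constant prediction
  at the response mean, zero support vectors) instead of failing.

## Cross-validation schemes

`loo_cv()` uses the hat-matrix shortcut for MLR and explicit refits for
everything else. `mfold_cv()` draws **one** balanced random partition
(fold sizes differing by at most one) and never repeats it for the same
model — repeated re-partitioning would smuggle extra averaging into
$Q^2_{LMO}$ and break comparability with single-partition practice. The
overlay axis `n_fitted` is the mean over folds of the cases fitted per
sub-model; for unequal folds this average is the single abscissa a curve
point needs. The package's default guidance is LOO for the linear
families (it is nearly free) and m-fold for networks and SVR (each fold
costs one optimization) — a default, not a restriction.

With replicated measurements, `grouped_cv()` offers `leave_sample_out`
(omit a whole replicate group per fold) and `loo_on_group_means`
(collapse groups to mean rows first). Ordinary leave-case-out on
replicated data leaks information — each held-out case has near-copies in
the training folds — and the package treats the grouped schemes as the
honest alternatives.

`rescale_to_fitted()` linearly interpolates the LOO median curve at the
LMO abscissae and reports gaps only inside the LOO `n_fitted` range;
extrapolation is refused (an LMO point below the smallest LOO abscissa is
dropped, and no overlap at all is an error).

## The sweep engine

One repetition at sample size $s$ is: draw $s$ cases without replacement
→ (optionally randomize) → split 80/20 → fit on the training part →
goodness of fit + configured CV on the training part + external metrics
on the test part. Design details that needed a decision:

- **Split rounding**: `n_train = round(0.8 s)` with R's round-half-to-even;
  the choice only matters for odd sizes and is recorded here once.
- **Group atomicity**: with replicate groups, draws and splits move whole
  groups; no group ever straddles a boundary.
- **RNG architecture**: a master seed deterministically derives one child
  stream per (spec, size, repetition), so results are independent of
  execution order and any single repetition can be reproduced alone.
- **Failure policy**: an individual fit failure is logged with its
  coordinates and skipped; the sweep aborts only past 50% failures at a
  size. Large repetition counts tolerate sporadic singular draws.
- **Summaries**: medians by default. Means are available, but badly
  modellable draws drag them; the median-vs-mean difference is itself a
  diagnostic of such cases (masking).
- **RMSE standardization**: `standardize_rmse = TRUE` divides the
  RMSE-family metrics by the training-response standard deviation. Within
  one dataset this is a harmless rescaling; across datasets it is what
  makes the extensive metrics comparable, and `overall_rank_table()`
  refuses to pool unstandardized records from several datasets.

`kennard_stone_split()` implements the deterministic max-min split
(standardized predictors, Euclidean distance, ties to the lowest index).
It is provided because representative-design splits are common practice —
and because they systematically place members of replicate pairs on
opposite sides of the split, which inflates external metrics; the random
split is the default throughout.

## Randomization nulls

Three schemes estimate chance correlation: `y_scramble` (permute the
response assignment; preserves the response multiset exactly),
`y_random` (draw each response from its empirical distribution) and
`x_random` (draw every predictor cell from its column distribution,
destroying inter-predictor correlation too). "From the distribution" is
implemented distribution-free as resampling with replacement, with a
fitted-normal mode available; `x_random` additionally offers a per-column
permutation mode that preserves column multisets exactly. Randomization is
applied to the drawn sample *before* splitting, so training and test sets
are both null and every metric of the record is a null metric. For OLS
the y-scrambling null has the analytic mean $E[R^2] = p/(n-1)$, which the
acceptance analysis checks by Monte Carlo and, at small $n$, against a
brute-force permutation oracle.

## Rank correlations

`spearman_rho()` is the Pearson correlation of average-ranked vectors
(the standard tie convention; no significance testing, since magnitudes
are what matter here). The 15 metric pairs over the six-metric panel are
generated programmatically. `overall_rank_table()` pools records per
family; `intraclass_rank_curves()` computes the correlations within
classes of repeated models (same dataset, spec, scheme, size) and flags
degenerate classes (a constant metric) instead of erroring. Classes need
at least 3 repetitions.

## The synthetic generator

`make_dataset()` emulates the structure of the numeric tables this kind
of study runs on: equicorrelated Gaussian predictors (default
equicorrelation 0.3, a mild descriptor-block collinearity), and a linear,
smooth-nonlinear, or shared-latent-factor response with i.i.d. noise.
Defaults — $p = 5$, unit noise, unit coefficient scale — give an
asymptotic $R^2$ near 0.85, in the range of a good QSAR model. The
latent-factor structure adds predictor measurement noise of sd 0.1, small
enough that the $k$ generating factors remain genuinely sufficient for a
fit (a full-rank linear model gains essentially nothing over them).
Badly modellable cases are emulated by shifting the response of a random
fraction of cases; replicated measurements by duplicating cases with
small within-group response noise.

What the generator does **not** emulate: discreteness and boundedness of
real molecular descriptors, heteroscedastic or correlated measurement
error, non-elliptical predictor clouds, and real applicability-domain
structure. Passing tests therefore demonstrate the *mechanics* of the
validation phenomena (overfitting inflation, null decay, overlay
collapse, allocation-driven decoupling) — they do not certify magnitudes
for any particular real dataset.

## Problem sizes in the shipped analyses

The test-suite and acceptance-script studies use: a 2000-case linear
dataset swept over sizes 30–500 (12 points, denser at the small end where
the curves are steep) with 500 repetitions per size and 2/5/10-fold CV; a
5000-case sample (100 repetitions) for the large-sample convergence of
the three aspects; 2000 scrambles for the permutation null; 200 paired
simulations for the replicate-leakage comparison; and three pooled
datasets with noise sd 0.25/1/4 — difficulty deliberately spread wide so
the pooled rank table reflects between-dataset structure regardless of
the seed — for the redundancy analysis. These sizes were chosen to put
Monte-Carlo error well inside the effects being demonstrated.

## Known limitations

- The ANN adapter exposes one activation and one optimizer (see above);
  hyperparameter scans over activations/optimizers are out of scope.
- No bootstrap robustness, repeated/double cross-validation, or
  permutation p-values: nulls are used as curves, not tests.
- PLS2 latent-count selection is the user's compromise; the package
  supplies curves, not a selector.
- `run_study()` exports flat CSV/JSON artifacts and basic plots; figure
  polishing beyond that is left to the user.
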