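# sizeval

Regression models in QSAR and related fields are judged on three aspects:
**goodness of fit** (how well the training responses are reproduced),
**robustness** (stability under internal resampling, i.e. cross-validation),
and **predictivity** (performance on an external test set). All three are
routinely summarized by a handful of validation parameters — but their
values depend strongly on the training-set size and on the model family,
and on small samples some of them are systematically misleading. `sizeval`
is a toolkit for studying exactly that dependence: it sweeps a dataset over
a series of sample sizes, fits models of four families, computes the full
metric panel on every draw, builds randomization nulls for chance
correlation, and quantifies how the metrics relate to one another.

It is aimed at modellers who want to know *which* validation parameters are
worth computing for *their* model type and sample size, and at
methodologists studying validation protocols themselves.

## The metric panel

For observed responses $y_i$, fitted values $\hat y_i$ and training mean
$\bar y$ ($n$ cases, $p$ optimized parameters excluding the intercept):

| aspect | intensive | extensive |
|---|---|---|
| goodness of fit | $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ | $\mathrm{RMSE} = \sqrt{\mathrm{RSS}/n}$ |
| robustness | $Q^2_{\mathrm{LOO}} = 1 - \mathrm{PRESS}/\mathrm{TSS}$, $Q^2_{\mathrm{LMO}}$ | $\mathrm{RMSE}_{\mathrm{LOO}} = \sqrt{\mathrm{PRESS}/n}$ |
| predictivity | $Q^2_{F2} = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y_{\mathrm{test}})^2$ | $\mathrm{RMSE}_{\mathrm{test}}$ |

with $\mathrm{PRESS} = \sum_i (y_i - \hat y_{i/i})^2$, the sum of squared
cross-validated residuals. For ordinary least squares the leave-one-out
residuals come free from one fit via the hat matrix,
$y_i - \hat y_{i/i} = e_i / (1 - h_{ii})$, and `press_hat_matrix()` uses
that identity (verified in the tests against explicit refitting to
1e-8).

Model families: multiple linear regression (OLS), two-block partial least
squares (NIPALS, one or several responses), single-hidden-layer neural
networks (via `nnet`), and epsilon support vector regression with an RBF
kernel (via `e1071`/libsvm), all behind one `model_spec()`/`fit_model()`
interface with family diagnostics (latent-variable count, convergence flag,
support-vector count).

Key phenomena the sweep engine exposes:

- **Small-sample inflation** — median training $R^2$ *decreases* with
  sample size while median $Q^2_{F2}$ increases; a high $R^2$ on a small
  sample is an overfitting artifact, not evidence of a good model.
- **Chance correlation** — on y-scrambled data the expected OLS $R^2$ is
  $p/(n-1)$, and the null curves quantify how much apparent performance is
  noise. Very flexible models are worse: small-epsilon SVR reaches training
  $R^2 > 0.9$ on fully randomized predictors while external $Q^2_{F2}$
  stays at or below zero, with the support-vector fraction near 1 as the
  warning signal.
- **The LOO/LMO rescaling law** — leave-one-out and m-fold curves collapse
  onto a single curve when plotted against `n_fitted`, the number of cases
  actually fitted per sub-model, so whichever scheme is computationally
  cheaper for the model family can stand in for the other.
- **Metric redundancy and the allocation effect** — Spearman rank
  correlations between the metrics, pooled (`overall_rank_table()`) or
  within classes of repeated models (`intraclass_rank_curves()`), show
  which parameters carry independent information; near-exhaustive sampling
  of a dataset with badly modellable cases drives the internal–external
  correlation negative.

## Worked example

```r
library(sizeval)

ds <- make_dataset(400, p = 5, noise_sd = 1, seed = 2024)   # linear truth
sw <- run_sweep(ds, model_spec("mlr"), sizes = c(30, 60, 120, 240),
                n_repeats = 100, cv = list(loo = TRUE, m = 5), seed = 11)
summarize_sweep(sw)
#>    spec  rand_scheme  size metric    value
#>  1 mlr   none           30 q2_f2     0.547
#>  2 mlr   none           30 q2_loo    0.561
#>  3 mlr   none           30 r2        0.758
#>  ...
#> 19 mlr   none          240 q2_f2     0.678
#> 20 mlr   none          240 q2_loo    0.672
#> 21 mlr   none          240 r2        0.692
```

Median $R^2$ falls from 0.758 at size 30 to 0.692 at size 240 while median
$Q^2_{F2}$ rises from 0.547 to 0.678: on small samples the fit flatters the
model and the external estimate is pessimistic; with enough data the three
aspects meet near the true explainable variance (about 0.69 here).

```r
rescale_to_fitted(summarize_cv_curves(sw))
#>   scheme n_fitted q2_lmo q2_loo      gap
#> 1 mfold5     38.4  0.634  0.623  0.0115
#> 2 mfold5     76.8  0.655  0.660 -0.00465
#> 3 mfold5    154.   0.671  0.668  0.00335
```

On the `n_fitted` axis the 5-fold curve sits on the leave-one-out curve to
within ~0.01. `autoplot(sw)`, `plot_overlay()` and `plot_rank_curves()`
draw the corresponding figures, and `run_study(study_config(...), out_dir)`
runs a whole configured study (sweep + nulls + overlay + rank tables) and
exports CSV/JSON artifacts.

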