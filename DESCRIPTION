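Package: sizeval
Title: Sample-Size Dependence of Regression Model Validation Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the three validation aspects of
    regression models -- goodness of fit, robustness under cross-validation,
    and external predictivity -- depend on training-set size and model
    family. Implements the R2/RMSE, Q2_LOO/Q2_LMO/RMSE_LOO and
    Q2_F2/RMSE_test metric families with the hat-matrix PRESS shortcut for
    linear models, uniform fit adapters for multiple linear regression,
    two-block partial least squares, single-hidden-layer neural networks and
    epsilon support vector regression, a resampling engine for sample-size
    sweeps with random or Kennard-Stone train/test splits, chance-correlation
    nulls by y-scrambling and x/y-randomization, rescaling of leave-many-out
    to leave-one-out cross-validation on the fitted-cases axis, and Spearman
    rank-correlation summaries of metric interdependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    nnet,
    e1071
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
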