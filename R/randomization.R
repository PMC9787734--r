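# Chance-correlation null schemes: any apparent performance of a model on
# randomized data is chance correlation, and its size dependence calibrates
# how much of the real-data performance could be noise.

#' Randomize a dataset to create a chance-correlation null
#'
#' Three null schemes, differing in what they destroy and what they keep:
#' \describe{
#'   \item{`y_scramble`}{A single uniform random permutation reassigns the
#'     response rows to other cases. The response multiset is preserved
#'     exactly; only the predictor-response link is destroyed. The cheapest
#'     scheme, and for linear models as effective as the other two.}
#'   \item{`y_random`}{Each response value is drawn independently from that
#'     response's empirical distribution (`mode = "bootstrap"`, sampling
#'     with replacement) or, with `mode = "normal"`, from a normal fitted to
#'     it.}
#'   \item{`x_random`}{Every predictor cell is drawn independently from its
#'     column's distribution, destroying both the inter-predictor and the
#'     predictor-response correlation and leaving a feature-less data cloud.
#'     `mode = "bootstrap"` resamples cells with replacement;
#'     `mode = "permutation"` instead permutes each column independently,
#'     which preserves every column multiset exactly;
#'     `mode = "normal"` draws from per-column fitted normals.}
#'   \item{`none`}{Identity; returns the dataset unchanged.}
#' }
#'
#' @param data A validation dataset.
#' @param scheme One of `"y_scramble"`, `"y_random"`, `"x_random"`,
#'   `"none"`.
#' @param mode Draw mode for the `*_random` schemes: `"bootstrap"`
#'   (default), `"permutation"` (x_random only), or `"normal"`.
#' @return A validation dataset of the same shape.
#' @examples
#' ds <- make_dataset(50, p = 3, seed = 1)
#' null <- randomize(ds, "y_scramble")
#' sort(null$y) - sort(ds$y) # all zero
#' @export
randomize <- function(data,
                      scheme = c("y_scramble", "y_random", "x_random", "none"),
                      mode = c("bootstrap", "permutation", "normal")) {
  assert_validation_dataset(data)
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (scheme == "none") return(data)
  n <- nrow(data)
  df <- as.data.frame(data)

  draw_col <- function(v) {
    switch(mode,
      bootstrap = sample(v, n, replace = TRUE),
      permutation = sample(v),
      normal = rnorm(n, mean(v), sd(v))
    )
  }

  if (scheme == "y_scramble") {
    perm <- sample.int(n)
    for (resp in vd_responses(data)) df[[resp]] <- df[[resp]][perm]
  } else if (scheme == "y_random") {
    if (mode == "permutation") {
      abort("permutation mode for responses is `y_scramble`")
    }
    for (resp in vd_responses(data)) df[[resp]] <- draw_col(df[[resp]])
  } else {
    for (pv in vd_predictors(data)) df[[pv]] <- draw_col(df[[pv]])
  }
  new_validation_dataset(df, vd_predictors(data), vd_responses(data),
                         vd_group_col(data))
}

#' Sample-size sweep on randomized (null) data
#'
#' Runs [run_sweep()] with each drawn sample randomized by the given
#' scheme(s) before splitting, so training and test sets are both null
#' data. The resulting curves — e.g. median training R-squared of
#' y-scrambled data against sample size — quantify chance correlation: for
#' linear models the null R2 decays like `p / (n - 1)`, while very flexible
#' models (small-epsilon SVR on x-randomized data) can hold near-perfect
#' training R2 with no predictivity.
#'
#' @inheritParams run_sweep
#' @param schemes Character vector of [randomize()] schemes (may include
#'   `"none"` for the paired non-null reference).
#' @param mode Draw mode for the `*_random` schemes.
#' @return A `sweep_result` whose records carry the scheme in
#'   `rand_scheme`.
#' @examples
#' ds <- make_dataset(200, p = 3, seed = 1)
#' nul <- chance_correlation_sweep(ds, model_spec("mlr"), sizes = 50,
#'                                 n_repeats = 20, schemes = "y_scramble",
#'                                 seed = 9)
#' median(nul$records$r2)
#' @export
chance_correlation_sweep <- function(data, specs, sizes, n_repeats = 500,
                                     schemes = "y_scramble",
                                     mode = "bootstrap",
                                     ratio = 0.8,
                                     cv = list(loo = TRUE, m = integer(0)),
                                     standardize_rmse = FALSE,
                                     seed = 1) {
  # the same master seed is passed to every scheme: each repetition then
  # draws the same subsample before randomization, so schemes are compared
  # on paired samples, and scheme "none" reproduces a plain run_sweep
  pieces <- lapply(seq_along(schemes), function(ci) {
    run_sweep(data, specs, sizes, n_repeats = n_repeats, ratio = ratio,
              cv = cv, randomization = schemes[ci],
              randomization_mode = mode,
              standardize_rmse = standardize_rmse,
              seed = seed)
  })
  out <- list(
    records = dplyr::bind_rows(lapply(pieces, function(p) p$records)),
    cv = dplyr::bind_rows(lapply(pieces, function(p) p$cv)),
    config = utils::modifyList(pieces[[1]]$config,
                               list(schemes = schemes, seed = seed))
  )
  attr(out, "failures") <- dplyr::bind_rows(
    lapply(pieces, function(p) attr(p, "failures")))
  class(out) <- "sweep_result"
  out
}
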