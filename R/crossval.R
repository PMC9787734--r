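# Cross-validation schemes and the n_fitted rescaling overlay.
#
# All Q2-type cross-validation statistics use TSS about the FULL training-set
# mean (not per-fold means): q2 = 1 - PRESS / TSS with
# PRESS = sum over cases of (y_i - yhat_{i, model not containing i})^2.

cv_result <- function(scheme, m, n_train, n_fitted, y_obs, y_cv) {
  q <- ncol(y_obs)
  q2 <- rmse <- numeric(q)
  for (j in seq_len(q)) {
    press <- sum((y_obs[, j] - y_cv[, j])^2)
    tss <- sum((y_obs[, j] - mean(y_obs[, j]))^2)
    q2[j] <- 1 - press / tss
    rmse[j] <- sqrt(press / nrow(y_obs))
  }
  out <- tibble::new_tibble(list(
    scheme = scheme, m = m, n_train = n_train, n_fitted = n_fitted,
    q2 = mean(q2), rmse_cv = mean(rmse)
  ), nrow = 1L)
  attr(out, "cv_predictions") <- y_cv
  attr(out, "q2_per_response") <- q2
  out
}

# refit-based cross-validated predictions for an arbitrary fold assignment
cv_predict_refit <- function(data, spec, fold_id) {
  if (spec$family == "mlr") {
    return(cv_predict_refit_ols(vd_X(data), vd_y(data), fold_id))
  }
  Y <- vd_Y(data)
  y_cv <- matrix(NA_real_, nrow(data), ncol(Y))
  for (f in unique(fold_id)) {
    hold <- which(fold_id == f)
    fit <- tryCatch(
      fit_model(vd_slice(data, -hold), spec),
      error = function(e) abort(paste0(
        "cross-validation sub-fit failed for held-out fold containing case ",
        hold[1], ": ", conditionMessage(e)))
    )
    pred <- predict(fit, vd_slice(data, hold))
    y_cv[hold, ] <- as.matrix(pred)
  }
  y_cv
}

# matrix fast path for OLS fold refits (numerically identical to routing
# each sub-fit through fit_model, just without the per-fold container cost)
cv_predict_refit_ols <- function(X, y, fold_id) {
  Xi <- cbind(1, as.matrix(X))
  n <- nrow(Xi)
  y_cv <- matrix(NA_real_, n, 1)
  for (f in unique(fold_id)) {
    hold <- which(fold_id == f)
    qrX <- qr(Xi[-hold, , drop = FALSE])
    if (qrX$rank < ncol(Xi)) {
      abort(paste0("cross-validation sub-fit failed for held-out fold ",
                   "containing case ", hold[1], ": singular design"))
    }
    cf <- qr.coef(qrX, y[-hold])
    y_cv[hold, 1] <- Xi[hold, , drop = FALSE] %*% cf
  }
  y_cv
}

#' Leave-one-out cross-validation
#'
#' Omits cases one at a time, predicts each omitted case from a model fitted
#' on the remaining `n_train - 1` cases, and summarizes
#' `Q2_LOO = 1 - PRESS / TSS` (TSS about the full training-set mean) and
#' `RMSE_LOO = sqrt(PRESS / n)`. For MLR the leave-one-out residuals are
#' obtained from a single fit through the hat-matrix identity
#' `e_i / (1 - h_ii)`; all other families are explicitly refitted `n` times.
#'
#' @param data A single- or multi-response validation dataset (the training
#'   set). Multi-response Q2 values are averaged; per-response values are in
#'   the `q2_per_response` attribute.
#' @param spec A [model_spec()].
#' @return A one-row tibble with columns `scheme` (`"loo"`), `m` (`NA`),
#'   `n_train`, `n_fitted` (`n_train - 1`), `q2`, `rmse_cv`, and the
#'   cross-validated predictions in the `cv_predictions` attribute.
#' @examples
#' ds <- make_dataset(40, p = 3, seed = 1)
#' loo_cv(ds, model_spec("mlr"))
#' @export
loo_cv <- function(data, spec) {
  assert_validation_dataset(data)
  n <- nrow(data)
  Y <- vd_Y(data)
  if (spec$family == "mlr") {
    y_cv <- matrix(ols_loo_predictions(vd_X(data), vd_y(data)), ncol = 1)
  } else {
    y_cv <- cv_predict_refit(data, spec, seq_len(n))
  }
  cv_result("loo", NA_integer_, n, n - 1, Y, y_cv)
}

#' m-fold (leave-many-out) cross-validation
#'
#' Partitions the training set once into `m` near-equal random folds (fold
#' sizes differ by at most one case; the partition is drawn a single time
#' and not repeated), predicts each fold from a model fitted on the
#' remaining folds, and summarizes `Q2_LMO` against TSS about the full
#' training-set mean. `n_fitted` — the average number of cases actually
#' fitted per sub-model, the abscissa on which LMO curves overlay the LOO
#' curve — is the mean over folds of `n_train - fold size`. With replicate
#' groups present, whole groups are assigned to folds so no group straddles
#' a fold boundary. `m = n_train` reproduces leave-one-out.
#'
#' @inheritParams loo_cv
#' @param m Number of folds, between 2 and `n_train`.
#' @return A one-row tibble as in [loo_cv()] with `scheme = "mfold"`.
#' @examples
#' ds <- make_dataset(50, p = 3, seed = 1)
#' set.seed(7)
#' mfold_cv(ds, model_spec("mlr"), m = 5)
#' @export
mfold_cv <- function(data, spec, m) {
  assert_validation_dataset(data)
  n <- nrow(data)
  if (m < 2 || m > n) abort("`m` must lie between 2 and n_train")
  groups <- vd_groups(data)
  if (is.null(groups)) {
    fold_id <- sample(rep_len(seq_len(m), n))
  } else {
    gl <- unique(groups)
    if (m > length(gl)) abort("`m` exceeds the number of replicate groups")
    g_fold <- sample(rep_len(seq_len(m), length(gl)))
    fold_id <- g_fold[match(groups, gl)]
  }
  y_cv <- cv_predict_refit(data, spec, fold_id)
  fold_sizes <- tabulate(fold_id, nbins = m)
  cv_result("mfold", as.integer(m), n, mean(n - fold_sizes), vd_Y(data), y_cv)
}

#' Cross-validation honouring replicate groups
#'
#' Two schemes for data with repeated measurements of the same sample.
#' `leave_sample_out` omits entire replicate groups at once, so a model
#' never sees any measurement of the sample it is asked to predict —
#' removing the information leakage that inflates naive leave-case-out Q2
#' on replicated data. `loo_on_group_means` first collapses each group to
#' its mean row (predictors and responses) and then runs ordinary
#' leave-one-out on the collapsed set.
#'
#' @inheritParams loo_cv
#' @param scheme `"leave_sample_out"` or `"loo_on_group_means"`.
#' @return A one-row tibble as in [loo_cv()].
#' @export
grouped_cv <- function(data, spec,
                       scheme = c("leave_sample_out", "loo_on_group_means")) {
  assert_validation_dataset(data)
  scheme <- match.arg(scheme)
  groups <- vd_groups(data)
  if (is.null(groups)) abort("`data` has no replicate-group column")
  gl <- unique(groups)
  if (length(gl) < 3) abort("need at least 3 replicate groups")
  n <- nrow(data)

  if (scheme == "leave_sample_out") {
    fold_id <- match(groups, gl)
    y_cv <- cv_predict_refit(data, spec, fold_id)
    fold_sizes <- tabulate(fold_id, nbins = length(gl))
    out <- cv_result("leave_sample_out", NA_integer_, n,
                     mean(n - fold_sizes), vd_Y(data), y_cv)
    return(out)
  }

  # collapse each group to its mean row, then ordinary LOO
  num_cols <- c(vd_predictors(data), vd_responses(data))
  df <- as.data.frame(data)
  collapsed <- do.call(rbind, lapply(gl, function(g) {
    colMeans(df[groups == g, num_cols, drop = FALSE])
  }))
  cd <- new_validation_dataset(as.data.frame(collapsed),
                               vd_predictors(data), vd_responses(data))
  res <- loo_cv(cd, spec)
  res$scheme <- "loo_on_group_means"
  res
}

#' Overlay LOO and LMO cross-validation curves on the n_fitted axis
#'
#' Leave-one-out and m-fold cross-validation measure the same thing at
#' different effective sample sizes: a sub-model in m-fold CV is fitted on
#' `n_train (1 - 1/m)` cases, one in LOO on `n_train - 1`. Re-indexing every
#' curve by `n_fitted` makes the LMO curves collapse onto the LOO curve.
#' This function takes summary curves (one `q2` per `(scheme, n_fitted)`),
#' linearly interpolates the LOO curve at each LMO abscissa inside the LOO
#' range, and reports the gap.
#'
#' @param curves A data frame with columns `scheme` (`"loo"` for the
#'   reference curve; anything else is treated as an LMO curve, e.g.
#'   `"mfold2"`), `n_fitted`, and `q2` (typically median Q2 over sweep
#'   repetitions, as produced by [summarize_sweep()]).
#' @return A tibble with one row per LMO point inside the LOO `n_fitted`
#'   range: `scheme`, `n_fitted`, `q2_lmo`, `q2_loo`
#'   (interpolated) and `gap = q2_lmo - q2_loo`. The per-scheme maximum
#'   absolute gap is in the `max_abs_gap` attribute. An empty tibble when
#'   there is nothing to compare; an error when no LMO abscissa falls inside
#'   the LOO range.
#' @export
rescale_to_fitted <- function(curves) {
  curves <- tibble::as_tibble(curves)
  need <- c("scheme", "n_fitted", "q2")
  if (!all(need %in% names(curves))) {
    abort("`curves` needs columns scheme, n_fitted, q2")
  }
  loo <- dplyr::filter(curves, .data$scheme == "loo") |>
    dplyr::arrange(.data$n_fitted)
  lmo <- dplyr::filter(curves, .data$scheme != "loo")
  if (nrow(loo) == 0) abort("`curves` contains no LOO reference curve")
  empty <- tibble::tibble(scheme = character(), n_fitted = numeric(),
                          q2_lmo = numeric(), q2_loo = numeric(),
                          gap = numeric())
  if (nrow(lmo) == 0) return(empty)
  inside <- lmo$n_fitted >= min(loo$n_fitted) & lmo$n_fitted <= max(loo$n_fitted)
  if (!any(inside)) {
    abort("no LMO point falls inside the LOO n_fitted range (empty overlap)")
  }
  lmo <- lmo[inside, ]
  interp <- stats::approx(loo$n_fitted, loo$q2, xout = lmo$n_fitted)$y
  out <- tibble::tibble(
    scheme = lmo$scheme,
    n_fitted = lmo$n_fitted,
    q2_lmo = lmo$q2,
    q2_loo = interp,
    gap = lmo$q2 - interp
  )
  gaps <- dplyr::summarise(dplyr::group_by(out, .data$scheme),
                           max_abs_gap = max(abs(.data$gap)), .groups = "drop")
  attr(out, "max_abs_gap") <- gaps
  out
}
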