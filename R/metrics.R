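#' Goodness-of-fit metrics for a training set
#'
#' Computes the sum-of-squares decomposition and the two standard
#' goodness-of-fit measures for observed vs modelled responses:
#' `RSS = sum((y - yhat)^2)`, `TSS = sum((y - mean(y))^2)`,
#' `MSS = sum((yhat - mean(yhat))^2)`, `R2 = 1 - RSS/TSS` and
#' `RMSE = sqrt(RSS/n)` (no degrees-of-freedom adjustment). The identity
#' `RSS + MSS = TSS`, and hence `0 <= R2 <= 1`, holds exactly only for
#' ordinary least squares fits with an intercept; for other model families
#' `R2` may be negative.
#'
#' @param y_obs Observed responses (numeric, length >= 2, positive variance).
#' @param y_hat Modelled responses on the same cases, same units.
#' @return A one-row tibble with columns `n`, `rss`, `mss`, `tss`, `r2`,
#'   `rmse`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
goodness_of_fit <- function(y_obs, y_hat) {
  check_response_pair(y_obs, y_hat)
  n <- length(y_obs)
  rss <- sum((y_obs - y_hat)^2)
  tss <- sum((y_obs - mean(y_obs))^2)
  mss <- sum((y_hat - mean(y_hat))^2)
  tibble::new_tibble(list(
    n = n, rss = rss, mss = mss, tss = tss,
    r2 = 1 - rss / tss,
    rmse = sqrt(rss / n)
  ), nrow = 1L)
}

#' External (test-set) predictivity metrics
#'
#' Computes `Q2_F2 = 1 - sum((y - yhat)^2) / sum((y - mean(y_test))^2)`,
#' where the denominator mean is taken over the test-set observations only,
#' and the test-set RMSE. `Q2_F2 <= 1` is the only bound; a value of 0 means
#' the model predicts no better than the test-set mean, and negative values
#' are worse than that.
#'
#' @param y_obs Observed test-set responses (positive variance).
#' @param y_hat Predictions for the same test cases.
#' @return A one-row tibble with columns `n_test`, `q2_f2`, `rmse_test`.
#' @examples
#' external_validation(c(0, 2), c(2, 0)) # q2_f2 = -3
#' @export
external_validation <- function(y_obs, y_hat) {
  check_response_pair(y_obs, y_hat)
  n <- length(y_obs)
  press <- sum((y_obs - y_hat)^2)
  tss <- sum((y_obs - mean(y_obs))^2)
  tibble::new_tibble(list(
    n_test = n,
    q2_f2 = 1 - press / tss,
    rmse_test = sqrt(press / n)
  ), nrow = 1L)
}

check_response_pair <- function(y_obs, y_hat) {
  if (length(y_obs) != length(y_hat)) {
    abort("`y_obs` and `y_hat` must have equal length")
  }
  if (length(y_obs) < 2) abort("need at least 2 cases")
  if (!all(is.finite(y_obs)) || !all(is.finite(y_hat))) {
    abort("responses must be finite")
  }
  if (var(y_obs) == 0) {
    abort("`y_obs` has zero variance: R2-type metrics are undefined")
  }
  invisible(NULL)
}

#' Leave-one-out PRESS for a linear model via the hat matrix
#'
#' For an ordinary least squares fit with intercept, the leave-one-out
#' cross-validated residual of case `i` is `e_i / (1 - h_ii)` where `e_i` is
#' the ordinary residual and `h_ii` the hat-matrix diagonal, so
#' `PRESS = sum((e_i / (1 - h_ii))^2)` without refitting the model `n`
#' times. Identical (to numerical tolerance) to explicit leave-one-out
#' refitting.
#'
#' @param X Predictor matrix (`n x p`, without intercept column; the
#'   intercept is handled internally). Must be full column rank with
#'   `n > p + 1`.
#' @param y Response vector.
#' @return The PRESS statistic (scalar).
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- rnorm(20)
#' press_hat_matrix(X, y)
#' @export
press_hat_matrix <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("`X` and `y` sizes disagree")
  if (n <= p + 1) abort("underdetermined: need n > p + 1")
  Xi <- cbind(1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) abort("singular design: X is rank deficient")
  e <- qr.resid(qrX, y)
  h <- stats::hat(Xi, intercept = FALSE)
  if (any(h >= 1 - 1e-12)) {
    abort("a hat diagonal equals 1: leave-one-out residual undefined")
  }
  sum((e / (1 - h))^2)
}

# internal: LOO-predicted responses from one OLS fit (hat-matrix shortcut)
ols_loo_predictions <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) abort("singular design: X is rank deficient")
  e <- qr.resid(qrX, y)
  h <- stats::hat(Xi, intercept = FALSE)
  if (any(h >= 1 - 1e-12)) {
    abort("a hat diagonal equals 1: leave-one-out residual undefined")
  }
  y - e / (1 - h)
}
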