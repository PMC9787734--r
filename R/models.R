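#' Specify a regression model family and its hyperparameters
#'
#' Builds the specification consumed by [fit_model()] and the sweep engine.
#' Four families are supported:
#' \describe{
#'   \item{`mlr`}{Multiple linear regression by unweighted ordinary least
#'     squares on all predictors, with a free intercept. No hyperparameters.}
#'   \item{`pls2`}{Two-block partial least squares (NIPALS): latent variable
#'     pairs extracted sequentially from the residual predictor and response
#'     matrices under a maximal-covariance criterion. Handles one or several
#'     responses. Hyperparameters: `n_latent` (required),
#'     `standardize_x`, `standardize_y` (default `TRUE`: autoscale each
#'     block before extraction; predictions are returned on the original
#'     response scale either way).}
#'   \item{`ann`}{Single-hidden-layer feed-forward network with logistic
#'     hidden units and a linear output, trained by the BFGS quasi-Newton
#'     optimizer of [nnet::nnet()]. Predictors and response are autoscaled
#'     internally. Hyperparameters: `n_hidden` (required; see
#'     [hidden_units_for()] for the weights-approximately-cases default
#'     rule), `decay` (L2 weight penalty, default 0), `maxit` (default 500),
#'     `reltol` (stopping tolerance, default 1e-8). Fits are stochastic via
#'     the random starting weights; seed the R RNG for reproducibility.}
#'   \item{`svr`}{Epsilon support vector regression with a Gaussian radial
#'     basis kernel ([e1071::svm()], libsvm). Hyperparameters: `gamma`
#'     (kernel width, default `1/p`), `epsilon` (tube half-width, default
#'     0.1), `cost` (regularization C, default 1), `shrinking` (default
#'     `TRUE`), `tolerance` (stopping, default 0.001). Inputs are autoscaled
#'     by the backend.}
#' }
#'
#' @param family One of `"mlr"`, `"pls2"`, `"ann"`, `"svr"`.
#' @param ... Family-specific hyperparameters, see above.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("mlr")
#' model_spec("pls2", n_latent = 2)
#' model_spec("svr", epsilon = 0.05, cost = 10)
#' @export
model_spec <- function(family = c("mlr", "pls2", "ann", "svr"), ...) {
  family <- match.arg(family)
  hp <- list(...)
  defaults <- switch(family,
    mlr  = list(),
    pls2 = list(n_latent = NULL, standardize_x = TRUE, standardize_y = TRUE),
    ann  = list(n_hidden = NULL, decay = 0, maxit = 500, reltol = 1e-8),
    svr  = list(gamma = NULL, epsilon = 0.1, cost = 1, shrinking = TRUE,
                tolerance = 0.001)
  )
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown hyperparameters for family '", family, "': ",
                 paste(unknown, collapse = ", ")))
  }
  hp <- utils::modifyList(defaults, hp)
  if (family == "pls2" && !is.null(hp$n_latent) && hp$n_latent < 1) {
    abort("`n_latent` must be a positive integer")
  }
  if (family == "ann" && !is.null(hp$n_hidden) && hp$n_hidden < 1) {
    abort("`n_hidden` must be a positive integer")
  }
  if (family == "svr") {
    if (!is.null(hp$gamma) && hp$gamma <= 0) abort("`gamma` must be positive")
    if (hp$cost <= 0) abort("`cost` must be positive")
    if (hp$epsilon < 0) abort("`epsilon` must be non-negative")
  }
  structure(list(family = family, hyperparameters = hp),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- x$hyperparameters
  hp_str <- if (length(hp) == 0) "" else
    paste0(": ", paste(names(hp), unlist(lapply(hp, format)),
                       sep = "=", collapse = ", "))
  cat("<model_spec ", x$family, hp_str, ">\n", sep = "")
  invisible(x)
}

# compact label used in sweep record tables
spec_label <- function(spec) {
  hp <- spec$hyperparameters
  hp <- hp[!vapply(hp, is.null, logical(1))]
  if (length(hp) == 0) return(spec$family)
  paste0(spec$family, "(",
         paste(names(hp), unlist(lapply(hp, format)), sep = "=",
               collapse = ","), ")")
}

#' Hidden-layer size giving roughly as many weights as cases
#'
#' A single-hidden-layer network with `H` hidden units on `p` inputs has
#' `(p + 1) * H + (H + 1) = H * (p + 2) + 1` weights. This helper returns
#' the `H` for which the weight count comes closest to a target number of
#' cases (typically the training-set size at the smallest sweep size), the
#' conventional way to fix network capacity in sample-size studies.
#'
#' @param p Number of predictors.
#' @param n_cases Target number of cases.
#' @return Integer number of hidden units (at least 1).
#' @examples
#' hidden_units_for(5, 30) # 4 hidden units = 29 weights
#' @export
hidden_units_for <- function(p, n_cases) {
  max(1L, as.integer(round((n_cases - 1) / (p + 2))))
}

ann_n_weights <- function(p, H) (p + 1L) * H + (H + 1L)

#' Fit a model specification to a dataset
#'
#' Uniform fitting front end: dispatches on the family of `spec` and returns
#' a fitted model exposing a common [predict()] contract plus the
#' diagnostics the validation analysis needs (optimized-parameter count,
#' latent-variable count, support-vector count and fraction, convergence
#' flag). MLR, PLS2 and SVR fits are deterministic; ANN fits are
#' deterministic conditional on the R RNG state.
#'
#' @param data A [as_validation_dataset()] dataset. Must be single-response
#'   for `mlr`, `ann` and `svr`.
#' @param spec A [model_spec()].
#' @return An object of class `sv_fit` with elements `spec`, `n_train`,
#'   `p_params`, `fitted` (training predictions, `n x q` matrix),
#'   `diagnostics` (named list) and the backend fit.
#' @examples
#' ds <- make_dataset(50, p = 3, seed = 1)
#' fit <- fit_model(ds, model_spec("mlr"))
#' glance(fit)
#' @export
fit_model <- function(data, spec) {
  assert_validation_dataset(data)
  if (!inherits(spec, "model_spec")) abort("`spec` must be a model_spec")
  X <- vd_X(data)
  if (anyNA(X)) abort("predictors contain missing values")
  fit <- switch(spec$family,
    mlr  = fit_mlr_impl(X, vd_y(data), spec),
    pls2 = fit_pls2_impl(X, vd_Y(data), spec),
    ann  = fit_ann_impl(X, vd_y(data), spec),
    svr  = fit_svr_impl(X, vd_y(data), spec)
  )
  fit$spec <- spec
  fit$n_train <- nrow(X)
  fit$predictor_names <- vd_predictors(data)
  fit$response_names <- vd_responses(data)
  fit$y_obs <- vd_Y(data)
  class(fit) <- "sv_fit"
  fit
}

#' @export
print.sv_fit <- function(x, ...) {
  cat("<sv_fit ", spec_label(x$spec), ": n_train=", x$n_train,
      ", p_params=", x$p_params, ">\n", sep = "")
  invisible(x)
}

# MLR -----------------------------------------------------------------------

fit_mlr_impl <- function(X, y, spec) {
  n <- nrow(X); p <- ncol(X)
  if (p < 1) abort("MLR needs at least one predictor")
  if (n <= p + 1) abort("underdetermined MLR: need n_train > p + 1")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) abort("singular design: X is rank deficient")
  coefs <- qr.coef(qrX, y)
  fitted <- drop(Xi %*% coefs)
  list(
    coefficients = coefs,
    qr = qrX,
    residuals = y - fitted,
    fitted = matrix(fitted, ncol = 1),
    p_params = p,
    diagnostics = list()
  )
}

# PLS2 (NIPALS) --------------------------------------------------------------

fit_pls2_impl <- function(X, Y, spec) {
  hp <- spec$hyperparameters
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  A <- hp$n_latent
  if (is.null(A)) abort("PLS2 requires `n_latent`")
  if (A > min(p, n - 1)) {
    abort("`n_latent` must not exceed min(p, n_train - 1)")
  }
  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  x_scale <- if (isTRUE(hp$standardize_x)) apply(X, 2, sd) else rep(1, p)
  y_scale <- if (isTRUE(hp$standardize_y)) apply(Y, 2, sd) else rep(1, q)
  if (any(x_scale == 0) || any(y_scale == 0)) {
    abort("zero-variance column: cannot standardize")
  }
  X0 <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  Y0 <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")

  W <- matrix(0, p, A); P <- matrix(0, p, A); C <- matrix(0, q, A)
  for (a in seq_len(A)) {
    u <- Y0[, which.max(colSums(Y0^2))]
    t_old <- rep(Inf, n)
    for (iter in 1:500) {
      w <- drop(crossprod(X0, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) abort("degenerate latent direction (zero covariance)")
      w <- w / nw
      t_sc <- drop(X0 %*% w)
      cc <- drop(crossprod(Y0, t_sc)) / sum(t_sc^2)
      if (q == 1) break
      u <- drop(Y0 %*% cc) / sum(cc^2)
      if (sum((t_sc - t_old)^2) < 1e-12 * sum(t_sc^2)) break
      t_old <- t_sc
    }
    p_a <- drop(crossprod(X0, t_sc)) / sum(t_sc^2)
    X0 <- X0 - tcrossprod(t_sc, p_a)
    Y0 <- Y0 - tcrossprod(t_sc, cc)
    W[, a] <- w; P[, a] <- p_a; C[, a] <- cc
  }
  # regression coefficients on the standardized scale
  B <- W %*% solve(crossprod(P, W), t(C))
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  fitted_s <- Xs %*% B
  fitted <- sweep(sweep(fitted_s, 2, y_scale, "*"), 2, y_center, "+")
  list(
    coefficients = B,
    scaling = list(x_center = x_center, x_scale = x_scale,
                   y_center = y_center, y_scale = y_scale),
    fitted = fitted,
    p_params = A * (p + ncol(Y)),
    diagnostics = list(n_latent = A)
  )
}

# ANN (nnet) ------------------------------------------------------------------

fit_ann_impl <- function(X, y, spec) {
  hp <- spec$hyperparameters
  p <- ncol(X)
  H <- hp$n_hidden %||% hidden_units_for(p, nrow(X))
  x_center <- colMeans(X); x_scale <- apply(X, 2, sd)
  if (any(x_scale == 0)) abort("zero-variance predictor: cannot standardize")
  y_center <- mean(y); y_scale <- sd(y)
  if (y_scale == 0) abort("zero-variance response")
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale
  nn <- nnet::nnet(Xs, ys, size = H, linout = TRUE, trace = FALSE,
                   maxit = hp$maxit, decay = hp$decay, reltol = hp$reltol,
                   MaxNWts = 1e5)
  fitted <- drop(nn$fitted.values) * y_scale + y_center
  list(
    backend = nn,
    scaling = list(x_center = x_center, x_scale = x_scale,
                   y_center = y_center, y_scale = y_scale),
    fitted = matrix(fitted, ncol = 1),
    p_params = ann_n_weights(p, H),
    diagnostics = list(n_hidden = H, converged = nn$convergence == 0)
  )
}

# SVR (e1071 / libsvm) --------------------------------------------------------

fit_svr_impl <- function(X, y, spec) {
  hp <- spec$hyperparameters
  gamma <- hp$gamma %||% (1 / ncol(X))
  sv <- tryCatch(
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
               gamma = gamma, epsilon = hp$epsilon, cost = hp$cost,
               shrinking = hp$shrinking, tolerance = hp$tolerance,
               scale = TRUE, fitted = TRUE),
    error = function(e) {
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
      else rlang::abort(conditionMessage(e))
    })
  if (is.null(sv)) {
    # the epsilon tube swallowed every case: no support vectors, and the
    # regression function degenerates to a constant at the response centre
    return(list(
      backend = list(constant = mean(y)),
      fitted = matrix(rep(mean(y), length(y)), ncol = 1),
      p_params = 1L,
      diagnostics = list(n_support_vectors = 0L, sv_fraction = 0)
    ))
  }
  n_sv <- length(sv$index)
  list(
    backend = sv,
    fitted = matrix(drop(sv$fitted), ncol = 1),
    p_params = max(1L, n_sv),
    diagnostics = list(n_support_vectors = n_sv,
                       sv_fraction = n_sv / nrow(X))
  )
}

# prediction -------------------------------------------------------------------

#' Predict from a fitted validation model
#'
#' @param object An `sv_fit` from [fit_model()].
#' @param newdata A validation dataset or data frame containing the
#'   predictor columns the model was trained on.
#' @param ... Unused.
#' @return A numeric vector of predictions for single-response models, or an
#'   `n x q` matrix for multi-response PLS2.
#' @export
predict.sv_fit <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[object$predictor_names])
  fam <- object$spec$family
  if (fam == "mlr") {
    return(drop(cbind(1, X) %*% object$coefficients))
  }
  if (fam == "pls2") {
    sc <- object$scaling
    Xs <- sweep(sweep(X, 2, sc$x_center), 2, sc$x_scale, "/")
    Ys <- Xs %*% object$coefficients
    out <- sweep(sweep(Ys, 2, sc$y_scale, "*"), 2, sc$y_center, "+")
    colnames(out) <- object$response_names
    return(if (ncol(out) == 1) drop(out) else out)
  }
  if (fam == "ann") {
    sc <- object$scaling
    Xs <- sweep(sweep(X, 2, sc$x_center), 2, sc$x_scale, "/")
    return(drop(predict(object$backend, Xs)) * sc$y_scale + sc$y_center)
  }
  if (!is.null(object$backend$constant)) {
    return(rep(object$backend$constant, nrow(X)))
  }
  drop(predict(object$backend, X))
}

# broom-style accessors ---------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameters of a fitted validation model
#'
#' For linear families (`mlr`, `pls2`) returns one row per coefficient (per
#' response for multi-response PLS2, on the original response scale). For
#' `ann` and `svr`, whose parameters are not individually interpretable,
#' returns the hyperparameters.
#'
#' @param x An `sv_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sv_fit <- function(x, ...) {
  fam <- x$spec$family
  if (fam == "mlr") {
    return(tibble::tibble(term = names(x$coefficients),
                          estimate = unname(x$coefficients)))
  }
  if (fam == "pls2") {
    sc <- x$scaling
    # back-transform standardized-scale coefficients to original units
    B <- x$coefficients * outer(1 / sc$x_scale, sc$y_scale)
    icept <- sc$y_center - drop(crossprod(B, sc$x_center))
    rows <- lapply(seq_along(x$response_names), function(j) {
      tibble::tibble(
        response = x$response_names[j],
        term = c("(Intercept)", x$predictor_names),
        estimate = c(icept[j], B[, j])
      )
    })
    return(dplyr::bind_rows(rows))
  }
  hp <- x$spec$hyperparameters
  hp <- hp[!vapply(hp, is.null, logical(1))]
  tibble::tibble(term = names(hp),
                 value = vapply(hp, function(v) as.numeric(v), numeric(1)))
}

#' One-row summary of a fitted validation model
#'
#' Reports the training goodness of fit together with the family-specific
#' diagnostics: latent-variable count (PLS2), hidden units and convergence
#' flag (ANN), support-vector count and fraction (SVR). A support-vector
#' fraction approaching 1 is a warning signal that the model is memorizing
#' rather than generalizing.
#'
#' @param x An `sv_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.sv_fit <- function(x, ...) {
  gof <- training_gof(x)
  base <- tibble::tibble(
    family = x$spec$family,
    n_train = x$n_train,
    p_params = x$p_params,
    r2 = gof$r2,
    rmse = gof$rmse
  )
  d <- x$diagnostics
  for (nm in names(d)) base[[nm]] <- d[[nm]]
  base
}

# training goodness of fit; multi-response fits report the per-response
# average (per-response values are available through goodness_of_fit directly)
training_gof <- function(fit) {
  q <- ncol(fit$y_obs)
  per <- lapply(seq_len(q), function(j) {
    goodness_of_fit(fit$y_obs[, j], fit$fitted[, j])
  })
  tibble::tibble(
    r2 = mean(vapply(per, function(g) g$r2, numeric(1))),
    rmse = mean(vapply(per, function(g) g$rmse, numeric(1)))
  )
}
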