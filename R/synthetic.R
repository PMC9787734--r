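#' Generate a synthetic modelling dataset
#'
#' Draws a dataset with the statistical structure typical of the numeric
#' tables used in regression validation studies: continuous, mutually
#' correlated predictors and one or more continuous responses depending on
#' them linearly or through a smooth nonlinearity, plus i.i.d. noise.
#' Optionally a fraction of badly modellable cases (response outliers) is
#' injected. The generating truth (coefficients or latent loadings) is
#' attached as an attribute so recovery can be tested, but it is kept out of
#' the data columns so pipeline code cannot consume it.
#'
#' Three structures are available:
#' \describe{
#'   \item{`linear`}{`y = X beta + eps` with `beta` drawn once from
#'     `N(0, coef_scale^2)`. The workhorse for MLR studies.}
#'   \item{`nonlinear_smooth`}{`y = coef_scale * (sin(x1) + x2^2) + eps`:
#'     smooth in two predictors, learnable by a small neural network or RBF
#'     support vector machine but misspecified for a linear model.}
#'   \item{`latent_factor_multiresponse`}{`q` responses and `p` predictors
#'     both generated from `n_latent` shared Gaussian factors, the natural
#'     test bed for two-block partial least squares.}
#' }
#'
#' Predictors are equicorrelated Gaussians:
#' `x_ij = sqrt(rho) g_i + sqrt(1-rho) z_ij` with `rho =
#' predictor_correlation` (ignored for the latent-factor structure, where
#' correlation comes from the factors).
#'
#' @param n Number of cases.
#' @param p Number of predictors (default 5).
#' @param q Number of responses (default 1; only the latent-factor structure
#'   uses `q > 1`).
#' @param structure One of `"linear"`, `"nonlinear_smooth"`,
#'   `"latent_factor_multiresponse"`.
#' @param predictor_correlation Equicorrelation of the predictors, in
#'   `[0, 1)`. Default 0.3, a mild collinearity typical of molecular
#'   descriptor blocks.
#' @param noise_sd Standard deviation of the additive response noise
#'   (response units). Default 1.
#' @param coef_scale Scale of the true coefficients (linear), of the smooth
#'   surface (nonlinear) or of the response loadings (latent). Default 1,
#'   which with the default `p = 5` gives a population signal-to-noise ratio
#'   around 5:1 (asymptotic R-squared near 0.85).
#' @param n_latent Number of shared latent factors for the multiresponse
#'   structure (default 2).
#' @param outlier_fraction Fraction of cases, in `[0, 0.2]`, whose response
#'   is shifted by `outlier_shift` to emulate badly modellable cases.
#' @param outlier_shift Response-unit shift applied to outlier cases.
#' @param seed Optional integer seed; the dataset is bit-reproducible given
#'   the seed.
#'
#' @return A [as_validation_dataset()] tibble with predictor columns
#'   `x1..xp` and response columns `y1..yq` (`y` when `q = 1`), carrying a
#'   `truth` attribute (list with the generating parameters) and an
#'   `outliers` attribute (integer indices of shifted cases).
#' @examples
#' ds <- make_dataset(100, p = 3, seed = 1)
#' attr(ds, "truth")$beta
#' @export
make_dataset <- function(n, p = 5, q = 1,
                         structure = c("linear", "nonlinear_smooth",
                                       "latent_factor_multiresponse"),
                         predictor_correlation = 0.3,
                         noise_sd = 1,
                         coef_scale = 1,
                         n_latent = 2,
                         outlier_fraction = 0,
                         outlier_shift = 0,
                         seed = NULL) {
  structure <- match.arg(structure)
  if (n < 3) abort("`n` must be at least 3")
  if (p < 1) abort("`p` must be at least 1")
  if (predictor_correlation < 0 || predictor_correlation >= 1) {
    abort("`predictor_correlation` must lie in [0, 1)")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (outlier_fraction < 0 || outlier_fraction > 0.2) {
    abort("`outlier_fraction` must lie in [0, 0.2]")
  }
  if (structure != "latent_factor_multiresponse" && q != 1) {
    abort("`q > 1` is only supported for the latent-factor structure")
  }
  if (structure == "latent_factor_multiresponse" && n_latent >= p) {
    abort("`n_latent` must be smaller than `p`")
  }
  if (n <= p) warn("`n <= p`: dataset is too small for a full linear fit")
  if (!is.null(seed)) set.seed(seed)

  rho <- predictor_correlation
  truth <- list(structure = structure, noise_sd = noise_sd,
                coef_scale = coef_scale, predictor_correlation = rho)

  if (structure == "latent_factor_multiresponse") {
    k <- n_latent
    Tm <- matrix(rnorm(n * k), n, k)
    A <- matrix(rnorm(p * k), p, k)
    B <- matrix(rnorm(q * k, sd = coef_scale), q, k)
    # small predictor measurement noise keeps the k factors genuinely
    # sufficient: a full-rank linear fit gains (almost) nothing over them
    X <- Tm %*% t(A) + matrix(rnorm(n * p, sd = 0.1), n, p)
    Y <- Tm %*% t(B) + matrix(rnorm(n * q, sd = noise_sd), n, q)
    truth$x_loadings <- A
    truth$y_loadings <- B
    truth$n_latent <- k
  } else {
    g <- rnorm(n)
    X <- sqrt(rho) * matrix(g, n, p) +
      sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    if (structure == "linear") {
      beta <- rnorm(p, sd = coef_scale)
      mu <- drop(X %*% beta)
      truth$beta <- beta
    } else {
      mu <- coef_scale * (sin(X[, 1]) + X[, min(2, p)]^2)
    }
    Y <- matrix(mu + rnorm(n, sd = noise_sd), n, 1)
  }

  out_idx <- integer(0)
  n_out <- floor(outlier_fraction * n)
  if (n_out > 0) {
    out_idx <- sample.int(n, n_out)
    Y[out_idx, ] <- Y[out_idx, ] + outlier_shift
  }

  xn <- paste0("x", seq_len(p))
  yn <- if (q == 1) "y" else paste0("y", seq_len(q))
  df <- tibble::as_tibble(as.data.frame(X, col.names = xn))
  names(df) <- xn
  for (j in seq_len(q)) df[[yn[j]]] <- Y[, j]

  ds <- new_validation_dataset(df, predictors = xn, responses = yn)
  attr(ds, "truth") <- truth
  attr(ds, "outliers") <- sort(out_idx)
  ds
}

#' Expand a dataset into replicated measurements
#'
#' Emulates experimental practice where each sample is measured several
#' times: every case is duplicated `replicates_per_case` times, each
#' replicate receiving independent response noise with standard deviation
#' `within_noise_sd`, and a replicate-group label tying the copies together.
#' The grouped dataset is what leave-sample-out cross-validation and
#' group-atomic splitting operate on.
#'
#' @param data A [as_validation_dataset()] dataset (ungrouped).
#' @param replicates_per_case Number of measurements per sample, at least 2.
#' @param within_noise_sd Standard deviation of the within-sample response
#'   noise; 0 gives exact duplicate rows.
#'
#' @return A grouped validation dataset with `n * replicates_per_case` rows
#'   and a `.sample` group column.
#' @export
add_replicates <- function(data, replicates_per_case, within_noise_sd = 0) {
  assert_validation_dataset(data)
  if (replicates_per_case < 2) abort("`replicates_per_case` must be >= 2")
  if (!is.null(vd_group_col(data))) abort("`data` is already grouped")
  n <- nrow(data)
  r <- replicates_per_case
  idx <- rep(seq_len(n), each = r)
  out <- as.data.frame(data)[idx, , drop = FALSE]
  for (resp in vd_responses(data)) {
    out[[resp]] <- out[[resp]] + rnorm(n * r, sd = within_noise_sd)
  }
  out$.sample <- idx
  rownames(out) <- NULL
  new_validation_dataset(out, vd_predictors(data), vd_responses(data),
                         group = ".sample")
}
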