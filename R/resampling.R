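# Sample-size sweep engine: random subsample -> train/test split -> fit ->
# full validation record, repeated per size and summarized.

# deterministic child-seed derivation: one stream per (spec, scheme, size,
# repetition) so repetitions are reproducible independently of execution
# order; kept below 2^31 - 1 (R integers are 32-bit)
derive_seed <- function(master, ...) {
  ix <- c(master, ...)
  s <- 0
  for (v in ix) s <- (s * 1000003 + (v + 1) * 2654435761) %% 2147483629
  as.integer(s %% 2147483629 + 1)
}

#' Draw a random subsample of a dataset
#'
#' Uniform sampling without replacement (no case appears twice in one
#' sample), in randomized order. With replicate groups present, sampling is
#' by whole groups: permuted groups are accumulated while the case count
#' stays within `size`, so no group is ever split.
#'
#' @param data A validation dataset.
#' @param size Number of cases to draw (at most `nrow(data)`).
#' @return A validation dataset with `size` rows (possibly fewer for grouped
#'   data, where only whole groups are taken).
#' @export
draw_sample <- function(data, size) {
  assert_validation_dataset(data)
  n <- nrow(data)
  if (size > n) abort("`size` exceeds the number of available cases")
  if (size < 2) abort("`size` must be at least 2")
  groups <- vd_groups(data)
  if (is.null(groups)) {
    return(vd_slice(data, sample.int(n, size)))
  }
  gl <- unique(groups)
  ord <- sample(gl)
  sizes <- tabulate(match(groups, ord), nbins = length(ord))
  keep <- ord[cumsum(sizes) <= size]
  if (length(keep) < 2) abort("`size` too small to hold two whole groups")
  idx <- which(groups %in% keep)
  vd_slice(data, sample(idx))
}

#' Split a dataset into training and test sets at random
#'
#' Disjoint, exhaustive random split with `n_train = round(ratio * n)`
#' (banker's rounding). With replicate groups, whole groups are assigned to
#' the training side until it holds at least `n_train` cases, so no group
#' straddles the boundary.
#'
#' @param data A validation dataset (typically a [draw_sample()] output).
#' @param ratio Training fraction, strictly between 0 and 1 (default 0.8,
#'   the conventional 80/20 split).
#' @return A list with elements `train` and `test`, both validation
#'   datasets.
#' @export
random_split <- function(data, ratio = 0.8) {
  assert_validation_dataset(data)
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must lie strictly in (0, 1)")
  n <- nrow(data)
  n_train <- round(ratio * n)
  if (n_train < 2 || n_train >= n) {
    abort("split leaves an empty or trivial training or test set")
  }
  groups <- vd_groups(data)
  if (is.null(groups)) {
    tr <- sample.int(n, n_train)
  } else {
    gl <- sample(unique(groups))
    sizes <- tabulate(match(groups, gl), nbins = length(gl))
    cum <- cumsum(sizes)
    k <- which(cum >= n_train)[1]
    if (is.na(k) || k >= length(gl)) {
      abort("grouped split leaves an empty test set")
    }
    tr <- which(groups %in% gl[seq_len(k)])
  }
  list(train = vd_slice(data, tr), test = vd_slice(data, -tr))
}

#' Kennard-Stone train/test split
#'
#' Deterministic max-min split in predictor space: predictors are
#' standardized internally, the two most Euclidean-distant cases seed the
#' training set, and cases are then added one at a time, each maximizing its
#' minimum distance to the current training set, until `n_train =
#' round(ratio * n)` is reached; the remainder is the test set. The
#' resulting training set spans the predictor space — and, as a known
#' consequence, members of a pair of near-duplicate (replicated) cases end
#' up on opposite sides of the split. Ties are broken by lowest row index.
#'
#' @inheritParams random_split
#' @return A list with elements `train` and `test`.
#' @export
kennard_stone_split <- function(data, ratio = 0.8) {
  assert_validation_dataset(data)
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must lie strictly in (0, 1)")
  n <- nrow(data)
  n_train <- round(ratio * n)
  if (n_train < 2 || n_train >= n) {
    abort("split leaves an empty or trivial training or test set")
  }
  X <- vd_X(data)
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  D <- as.matrix(stats::dist(Xs))
  # seed: the most distant pair; which.max on the matrix is index-ordered,
  # so ties resolve to the lowest indices
  start <- arrayInd(which.max(D), dim(D))
  sel <- sort(start[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  list(train = vd_slice(data, sel), test = vd_slice(data, -sel))
}

#' Run a sample-size validation sweep
#'
#' The engine of the sample-size study. For every combination of sample
#' size, repetition and model specification it: draws a random subsample of
#' `size` cases, optionally randomizes it (see [randomize()]), splits it
#' 80/20 (or per `ratio`/`split_method`) into training and test sets, fits
#' the model on the training set, and computes the full validation record —
#' goodness of fit (R2, RMSE) on the training set, the configured
#' cross-validation statistics (Q2_LOO/RMSE_LOO and Q2_LMO per fold count)
#' on the training set, and external predictivity (Q2_F2, RMSE_test) on the
#' test set. Each repetition runs under its own deterministic child RNG
#' stream derived from `seed`, so results do not depend on execution order
#' and any single repetition can be reproduced in isolation.
#'
#' Individual fit failures are logged (attribute `failures`) rather than
#' fatal; the sweep aborts only if more than half the repetitions at some
#' size fail.
#'
#' @param data A validation dataset to subsample from.
#' @param specs A [model_spec()] or list of them.
#' @param sizes Integer vector of sample sizes (each <= `nrow(data)`).
#' @param n_repeats Repetitions per size (default 500).
#' @param ratio Training fraction of each sample (default 0.8).
#' @param split_method `"random"` or `"kennard_stone"`.
#' @param cv List controlling cross-validation: `loo` (logical, default
#'   `TRUE`) and `m` (integer vector of fold counts for leave-many-out,
#'   default none).
#' @param randomization `"none"` (default) or one of the [randomize()]
#'   schemes; applied to each drawn sample before splitting, so both
#'   training and test sets are null data.
#' @param randomization_mode Passed to [randomize()].
#' @param standardize_rmse If `TRUE`, RMSE-like metrics are computed on
#'   responses standardized by the training-set standard deviation, making
#'   them comparable across datasets and required when pooling records for
#'   rank correlations across datasets.
#' @param seed Master seed (integer).
#' @return A `sweep_result`: list with tibbles `records` (one row per size
#'   x repetition x spec with all metrics and model diagnostics) and `cv`
#'   (long form, one row per cross-validation scheme evaluation with
#'   `n_fitted`), plus the configuration. Failed repetitions are in
#'   `attr(, "failures")`.
#' @examples
#' ds <- make_dataset(300, p = 3, seed = 1)
#' sw <- run_sweep(ds, model_spec("mlr"), sizes = c(30, 100),
#'                 n_repeats = 5, seed = 42)
#' summarize_sweep(sw)
#' @export
run_sweep <- function(data, specs, sizes, n_repeats = 500, ratio = 0.8,
                      split_method = c("random", "kennard_stone"),
                      cv = list(loo = TRUE, m = integer(0)),
                      randomization = "none",
                      randomization_mode = "bootstrap",
                      standardize_rmse = FALSE,
                      seed = 1) {
  assert_validation_dataset(data)
  split_method <- match.arg(split_method)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (is.unsorted(sizes)) sizes <- sort(sizes)
  if (max(sizes) > nrow(data)) abort("a sweep size exceeds the dataset size")
  do_loo <- isTRUE(cv$loo %||% TRUE)
  m_vec <- as.integer(cv$m %||% integer(0))

  records <- list()
  cv_rows <- list()
  failures <- list()

  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (zi in seq_along(sizes)) {
      size <- sizes[zi]
      n_fail <- 0
      for (r in seq_len(n_repeats)) {
        set.seed(derive_seed(seed, si, zi, r))
        res <- tryCatch(
          sweep_one(data, spec, size, ratio, split_method, do_loo, m_vec,
                    randomization, randomization_mode, standardize_rmse),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          n_fail <- n_fail + 1
          failures[[length(failures) + 1]] <- tibble::tibble(
            spec = spec_label(spec), size = size, repetition = r,
            scheme = randomization, message = conditionMessage(res)
          )
          next
        }
        res$record$repetition <- r
        res$record$size <- size
        res$record$spec <- spec_label(spec)
        records[[length(records) + 1]] <- res$record
        if (nrow(res$cv) > 0) {
          res$cv$repetition <- r
          res$cv$size <- size
          res$cv$spec <- spec_label(spec)
          cv_rows[[length(cv_rows) + 1]] <- res$cv
        }
      }
      if (n_fail > n_repeats / 2) {
        abort(sprintf(
          "sweep aborted: %d of %d fits failed at size %d for %s",
          n_fail, n_repeats, size, spec_label(spec)))
      }
    }
  }

  out <- list(
    records = dplyr::bind_rows(records),
    cv = dplyr::bind_rows(cv_rows),
    config = list(sizes = sizes, n_repeats = n_repeats, ratio = ratio,
                  split_method = split_method, cv = list(loo = do_loo, m = m_vec),
                  randomization = randomization,
                  randomization_mode = randomization_mode,
                  standardize_rmse = standardize_rmse, seed = seed,
                  specs = vapply(specs, spec_label, character(1)))
  )
  attr(out, "failures") <- dplyr::bind_rows(failures)
  class(out) <- "sweep_result"
  out
}

# one (size, repetition, spec) evaluation under an already-seeded RNG
sweep_one <- function(data, spec, size, ratio, split_method, do_loo, m_vec,
                      randomization, randomization_mode, standardize_rmse) {
  sub <- draw_sample(data, size)
  if (randomization != "none") {
    sub <- randomize(sub, randomization, mode = randomization_mode)
  }
  parts <- if (split_method == "random") random_split(sub, ratio)
           else kennard_stone_split(sub, ratio)
  train <- parts$train
  test <- parts$test

  fit <- fit_model(train, spec)
  q <- length(vd_responses(train))
  y_scale <- if (standardize_rmse) {
    mean(apply(vd_Y(train), 2, sd))
  } else 1

  # goodness of fit (per-response averaged for multi-response)
  gof <- training_gof(fit)
  ext <- {
    Yte <- vd_Y(test)
    pred <- as.matrix(predict(fit, test))
    per <- lapply(seq_len(q), function(j) external_validation(Yte[, j], pred[, j]))
    list(
      q2_f2 = mean(vapply(per, function(x) x$q2_f2, numeric(1))),
      rmse_test = mean(vapply(per, function(x) x$rmse_test, numeric(1)))
    )
  }

  cvs <- list()
  if (do_loo) cvs[["loo"]] <- loo_cv(train, spec)
  for (m in m_vec) {
    if (m <= nrow(train)) cvs[[paste0("mfold", m)]] <- mfold_cv(train, spec, m)
  }
  cv_tbl <- if (length(cvs) > 0) dplyr::bind_rows(cvs) else
    tibble::tibble(scheme = character(), m = integer(), n_train = integer(),
                   n_fitted = numeric(), q2 = numeric(), rmse_cv = numeric())
  if (nrow(cv_tbl) > 0) {
    cv_tbl$rmse_cv <- cv_tbl$rmse_cv / y_scale
    cv_tbl$rand_scheme <- randomization
  }

  loo_row <- if (do_loo) cvs[["loo"]] else NULL
  record <- tibble::new_tibble(list(
    family = spec$family,
    rand_scheme = randomization,
    n_train = nrow(train),
    n_test = nrow(test),
    r2 = gof$r2,
    rmse = gof$rmse / y_scale,
    q2_loo = if (!is.null(loo_row)) loo_row$q2 else NA_real_,
    rmse_loo = if (!is.null(loo_row)) loo_row$rmse_cv / y_scale else NA_real_,
    q2_f2 = ext$q2_f2,
    rmse_test = ext$rmse_test / y_scale,
    p_params = fit$p_params,
    rmse_standardized = standardize_rmse
  ), nrow = 1L)
  for (nm in names(fit$diagnostics)) record[[nm]] <- fit$diagnostics[[nm]]
  list(record = record, cv = cv_tbl)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %d records, %d cv rows, sizes %s>\n",
              nrow(x$records), nrow(x$cv),
              paste(x$config$sizes, collapse = "/")))
  invisible(x)
}

#' Summarize sweep records per sample size
#'
#' Collapses the repetitions of a sweep to per-(spec, scheme, size) summary
#' curves. The median is the default statistic: it is robust to the badly
#' modellable outlier draws that drag means around.
#'
#' @param sweep A [run_sweep()] result.
#' @param statistic `"median"`, `"mean"` or `"quartiles"` (quartiles always
#'   include the median).
#' @return A long tibble with columns `spec`, `rand_scheme`, `size`,
#'   `metric`, and `value` (plus `q25`/`q75` for `"quartiles"`).
#' @export
summarize_sweep <- function(sweep, statistic = c("median", "mean", "quartiles")) {
  statistic <- match.arg(statistic)
  if (!inherits(sweep, "sweep_result")) abort("`sweep` must be a sweep_result")
  if (nrow(sweep$records) == 0) abort("sweep has no records")
  metrics <- intersect(
    c("r2", "rmse", "q2_loo", "rmse_loo", "q2_f2", "rmse_test"),
    names(sweep$records))
  long <- tidyr::pivot_longer(
    sweep$records[c("spec", "rand_scheme", "size", metrics)],
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  g <- dplyr::group_by(long, .data$spec, .data$rand_scheme, .data$size,
                       .data$metric)
  out <- switch(statistic,
    median = dplyr::summarise(g, value = median(.data$value), .groups = "drop"),
    mean = dplyr::summarise(g, value = mean(.data$value), .groups = "drop"),
    quartiles = dplyr::summarise(
      g,
      q25 = quantile(.data$value, 0.25, names = FALSE),
      value = median(.data$value),
      q75 = quantile(.data$value, 0.75, names = FALSE),
      .groups = "drop")
  )
  out
}

#' Summarize cross-validation curves for the n_fitted overlay
#'
#' Collapses the long cross-validation rows of a sweep to one median point
#' per (spec, scheme, size), labelled for [rescale_to_fitted()]: the LOO
#' rows keep scheme `"loo"`, m-fold rows become `"mfold<m>"`.
#'
#' @param sweep A [run_sweep()] result with cross-validation configured.
#' @return A tibble with columns `spec`, `rand_scheme`, `scheme`, `size`,
#'   `n_train`, `n_fitted`, `q2`, `rmse_cv` (medians over repetitions).
#' @export
summarize_cv_curves <- function(sweep) {
  if (!inherits(sweep, "sweep_result")) abort("`sweep` must be a sweep_result")
  if (nrow(sweep$cv) == 0) abort("sweep has no cross-validation rows")
  cv <- sweep$cv
  cv$scheme <- ifelse(cv$scheme == "mfold", paste0("mfold", cv$m), cv$scheme)
  dplyr::summarise(
    dplyr::group_by(cv, .data$spec, .data$rand_scheme, .data$scheme,
                    .data$size),
    n_train = median(.data$n_train),
    n_fitted = median(.data$n_fitted),
    q2 = median(.data$q2),
    rmse_cv = median(.data$rmse_cv),
    .groups = "drop")
}
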