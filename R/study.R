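# Study orchestration: dataset loading, declarative configuration, and
# one-call execution of sweep + nulls + overlay + rank correlations with
# artifact export.

#' Load a numeric modelling dataset from CSV
#'
#' Reads a plain numeric table, optionally one-hot encodes declared
#' categorical predictor columns, drops rows with missing values in any
#' used column (counted and reported), and returns a role-annotated
#' validation dataset.
#'
#' @param path Path to a CSV file with a header row.
#' @param predictors Character vector of predictor column names (including
#'   any categorical ones listed in `categoricals`).
#' @param responses Character vector of response column names.
#' @param group Optional replicate-group column name.
#' @param categoricals Character vector of predictor columns to one-hot
#'   encode (one indicator column per level).
#' @return A [as_validation_dataset()] dataset; the number of dropped rows
#'   is in the `n_dropped` attribute.
#' @export
load_csv_dataset <- function(path, predictors, responses, group = NULL,
                             categoricals = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  used <- c(predictors, responses, group)
  missing_cols <- setdiff(used, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[used]
  keep <- stats::complete.cases(raw)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing values dropped")
  }
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0) abort("no complete rows left after dropping missing values")

  num_preds <- setdiff(predictors, categoricals)
  for (cc in num_preds) {
    if (!is.numeric(raw[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[cc]]))))[1]
      abort(sprintf("non-numeric value in numeric column '%s' (row %s)",
                    cc, bad %||% "?"))
    }
  }
  for (cc in categoricals %||% character(0)) {
    lv <- sort(unique(as.character(raw[[cc]])))
    for (l in lv) {
      raw[[paste0(cc, "_", l)]] <- as.numeric(as.character(raw[[cc]]) == l)
    }
    num_preds <- c(num_preds, paste0(cc, "_", lv))
    raw[[cc]] <- NULL
  }
  ds <- as_validation_dataset(raw, predictors = num_preds,
                              responses = responses, group = group)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Declare a validation study
#'
#' Collects everything [run_study()] needs into one declarative object: the
#' dataset (in memory, or a synthetic recipe), the model specifications,
#' the sample-size series and repetition count, the split and
#' cross-validation settings, the randomization null schemes, and the
#' master seed.
#'
#' @param dataset A validation dataset, or a named list of [make_dataset()]
#'   arguments to generate one.
#' @param specs A [model_spec()] or list of them.
#' @param sizes Ascending integer vector of sample sizes.
#' @param n_repeats Repetitions per size (default 500).
#' @param ratio Training fraction (default 0.8).
#' @param split_method `"random"` or `"kennard_stone"`.
#' @param cv List with `loo` (logical) and `m` (fold counts).
#' @param randomization_schemes Character vector of null schemes to run in
#'   addition to the real-data sweep (default none).
#' @param statistic Summary statistic (default `"median"`).
#' @param standardize_rmse Compute RMSE metrics on standardized responses.
#' @param seed Master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(dataset, specs, sizes, n_repeats = 500, ratio = 0.8,
                         split_method = "random",
                         cv = list(loo = TRUE, m = integer(0)),
                         randomization_schemes = character(0),
                         statistic = "median",
                         standardize_rmse = FALSE,
                         seed = 1) {
  if (is.list(dataset) && !inherits(dataset, "validation_dataset")) {
    dataset <- do.call(make_dataset, dataset)
  }
  assert_validation_dataset(dataset)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (length(sizes) < 1 || any(sizes > nrow(dataset))) {
    abort("`sizes` must be non-empty and no size may exceed the dataset size")
  }
  structure(list(
    dataset = dataset, specs = specs, sizes = sort(sizes),
    n_repeats = n_repeats, ratio = ratio, split_method = split_method,
    cv = cv, randomization_schemes = randomization_schemes,
    statistic = statistic, standardize_rmse = standardize_rmse, seed = seed
  ), class = "study_config")
}

#' Execute a validation study and export its artifacts
#'
#' Runs the sample-size sweep (and, if configured, the randomization null
#' sweeps), the leave-many-out/leave-one-out overlay, the summary curves,
#' and both rank-correlation analyses, and writes the results as plain
#' files under `out_dir`: `records.csv` (one row per fitted model),
#' `summary.csv`, `cv_curves.csv`, `overlay_gap.csv`, `rank_overall.csv`,
#' `rank_intraclass.csv` and `manifest.json` (configuration, seed, package
#' version). Re-running with the same configuration reproduces the record
#' tables exactly.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed objects (`sweep`, `summary`,
#'   `cv_curves`, `overlay`, `rank_overall`, `rank_intraclass`) and the file
#'   paths; the `status` element is `"ok"` or `"partial"` (some repetitions
#'   failed — see `failures`).
#' @export
run_study <- function(config, out_dir) {
  if (!inherits(config, "study_config")) abort("`config` must be a study_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sweep <- run_sweep(
    config$dataset, config$specs, config$sizes,
    n_repeats = config$n_repeats, ratio = config$ratio,
    split_method = config$split_method, cv = config$cv,
    standardize_rmse = config$standardize_rmse, seed = config$seed)

  if (length(config$randomization_schemes) > 0) {
    nulls <- chance_correlation_sweep(
      config$dataset, config$specs, config$sizes,
      n_repeats = config$n_repeats, schemes = config$randomization_schemes,
      ratio = config$ratio, cv = config$cv,
      standardize_rmse = config$standardize_rmse, seed = config$seed)
    sweep$records <- dplyr::bind_rows(sweep$records, nulls$records)
    sweep$cv <- dplyr::bind_rows(sweep$cv, nulls$cv)
    attr(sweep, "failures") <- dplyr::bind_rows(
      attr(sweep, "failures"), attr(nulls, "failures"))
  }

  summary_tbl <- summarize_sweep(sweep, config$statistic)
  cv_curves <- if (nrow(sweep$cv) > 0) summarize_cv_curves(sweep) else NULL
  overlay <- NULL
  if (!is.null(cv_curves)) {
    real <- dplyr::filter(cv_curves, .data$rand_scheme == "none")
    if (any(real$scheme != "loo") && any(real$scheme == "loo")) {
      overlay <- rescale_to_fitted(real)
    }
  }
  rank_overall <- overall_rank_table(sweep$records[
    sweep$records$rand_scheme == "none", ])
  rank_intraclass <- intraclass_rank_curves(sweep)

  paths <- list(
    records = file.path(out_dir, "records.csv"),
    summary = file.path(out_dir, "summary.csv"),
    cv_curves = file.path(out_dir, "cv_curves.csv"),
    overlay_gap = file.path(out_dir, "overlay_gap.csv"),
    rank_overall = file.path(out_dir, "rank_overall.csv"),
    rank_intraclass = file.path(out_dir, "rank_intraclass.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(sweep$records, paths$records, row.names = FALSE)
  utils::write.csv(summary_tbl, paths$summary, row.names = FALSE)
  if (!is.null(cv_curves)) {
    utils::write.csv(cv_curves, paths$cv_curves, row.names = FALSE)
  }
  if (!is.null(overlay)) {
    utils::write.csv(overlay, paths$overlay_gap, row.names = FALSE)
  }
  utils::write.csv(rank_overall, paths$rank_overall, row.names = FALSE)
  utils::write.csv(rank_intraclass, paths$rank_intraclass, row.names = FALSE)

  failures <- attr(sweep, "failures")
  manifest <- list(
    package = "sizeval",
    version = as.character(utils::packageVersion("sizeval")),
    r_version = R.version.string,
    seed = config$seed,
    sizes = config$sizes,
    n_repeats = config$n_repeats,
    ratio = config$ratio,
    split_method = config$split_method,
    cv = config$cv,
    randomization_schemes = config$randomization_schemes,
    standardize_rmse = config$standardize_rmse,
    specs = vapply(config$specs, spec_label, character(1)),
    n_failures = nrow(failures)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(
    sweep = sweep, summary = summary_tbl, cv_curves = cv_curves,
    overlay = overlay, rank_overall = rank_overall,
    rank_intraclass = rank_intraclass, paths = paths,
    failures = failures,
    status = if (nrow(failures) == 0) "ok" else "partial"
  ))
}
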