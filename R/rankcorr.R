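# Spearman rank correlations between validation parameters: overall pools
# of models, and intra-class curves (repetitions sharing dataset, model
# spec and sample size) against sample size.

validation_metrics <- c("r2", "rmse", "q2_loo", "rmse_loo",
                        "q2_f2", "rmse_test")

# the full pair set over the six metrics (15 pairs), generated not listed
metric_pairs <- function(metrics = validation_metrics) {
  cmb <- utils::combn(metrics, 2)
  tibble::tibble(metric_a = cmb[1, ], metric_b = cmb[2, ])
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average-ranked vectors (ties receive average
#' ranks). Rank correlation measures the monotone — not necessarily linear
#' — association between two validation parameters, which is why it is used
#' to compare metrics with very different scales and response curves.
#'
#' @param a,b Equal-length finite numeric vectors, length >= 3.
#' @return The rank correlation coefficient in `[-1, 1]`.
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 2, 1)) # -1
#' spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4)) # 0.8 with average ranks
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  if (length(a) < 3) abort("need at least 3 observations")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("inputs must be finite")
  if (var(rank(a)) == 0 || var(rank(b)) == 0) {
    abort("zero rank variance: correlation undefined")
  }
  cor(a, b, method = "spearman")
}

#' Overall rank correlations between validation parameters
#'
#' Pools validation records of one model family — across sizes,
#' repetitions, and (optionally) datasets — and computes the Spearman rank
#' correlation for every configured metric pair. When records from several
#' datasets are pooled, the RMSE-like metrics are only comparable if they
#' were computed on standardized responses (`standardize_rmse = TRUE` in
#' [run_sweep()]); mixing standardized and raw records is an error.
#'
#' @param records A record tibble from one or more [run_sweep()] results
#'   (rows of `$records`, optionally with a `dataset` column when several
#'   sources are pooled).
#' @param pairs Optional two-column data frame (`metric_a`, `metric_b`)
#'   restricting the pair set; default all 15 pairs over the six metrics.
#' @return A tibble with one row per family and pair: `family`, `metric_a`,
#'   `metric_b`, `rho`, `n_models`.
#' @export
overall_rank_table <- function(records, pairs = NULL) {
  records <- tibble::as_tibble(records)
  pairs <- if (is.null(pairs)) metric_pairs() else tibble::as_tibble(pairs)
  if ("rmse_standardized" %in% names(records)) {
    std <- unique(records$rmse_standardized)
    if (length(std) > 1) {
      abort("cannot pool records with mixed RMSE standardization")
    }
    n_datasets <- if ("dataset" %in% names(records))
      length(unique(records$dataset)) else 1
    if (n_datasets > 1 && !isTRUE(std)) {
      abort(paste0("pooling across datasets requires RMSE metrics computed ",
                   "on standardized responses (standardize_rmse = TRUE)"))
    }
  }
  metrics <- unique(c(pairs$metric_a, pairs$metric_b))
  missing_m <- setdiff(metrics, names(records))
  if (length(missing_m) > 0) {
    abort(paste0("records lack metric columns: ",
                 paste(missing_m, collapse = ", ")))
  }
  fams <- unique(records$family)
  out <- lapply(fams, function(fam) {
    sub <- records[records$family == fam, ]
    rho <- mapply(function(a, b) {
      ok <- is.finite(sub[[a]]) & is.finite(sub[[b]])
      if (sum(ok) < 3) return(NA_real_)
      spearman_rho(sub[[a]][ok], sub[[b]][ok])
    }, pairs$metric_a, pairs$metric_b)
    tibble::tibble(family = fam, metric_a = pairs$metric_a,
                   metric_b = pairs$metric_b, rho = unname(rho),
                   n_models = nrow(sub))
  })
  dplyr::bind_rows(out)
}

#' Intra-class rank correlation curves against sample size
#'
#' A class is the set of repeated models sharing dataset, model
#' specification, randomization scheme and sample size; within each class
#' the Spearman correlation of every metric pair is computed across the
#' repetitions and emitted as size-indexed curves. These curves expose two
#' regimes: goodness of fit and cross-validation metrics couple
#' increasingly tightly as the training set grows, while internal and
#' external metrics decouple — and turn negative — when the sample nearly
#' exhausts the dataset and the train/test allocation of badly modellable
#' cases dominates (the allocation problem).
#'
#' Classes in which a metric is constant across repetitions (zero rank
#' variance) get `rho = NA` and `degenerate = TRUE` rather than an error.
#'
#' @param sweep A [run_sweep()] result (or a bare record tibble).
#' @param pairs Optional pair restriction as in [overall_rank_table()].
#' @return A tibble with columns `spec`, `rand_scheme`, `size`, `metric_a`,
#'   `metric_b`, `rho`, `n_models`, `degenerate`.
#' @export
intraclass_rank_curves <- function(sweep, pairs = NULL) {
  records <- if (inherits(sweep, "sweep_result")) sweep$records
             else tibble::as_tibble(sweep)
  pairs <- if (is.null(pairs)) metric_pairs() else tibble::as_tibble(pairs)
  metrics <- unique(c(pairs$metric_a, pairs$metric_b))
  key_cols <- intersect(c("dataset", "spec", "rand_scheme", "size"),
                        names(records))
  classes <- dplyr::group_split(dplyr::group_by(
    records, dplyr::across(dplyr::all_of(key_cols))))
  out <- lapply(classes, function(cls) {
    if (nrow(cls) < 3) return(NULL)
    res <- pairs
    res$rho <- NA_real_
    res$degenerate <- FALSE
    for (i in seq_len(nrow(pairs))) {
      a <- cls[[pairs$metric_a[i]]]
      b <- cls[[pairs$metric_b[i]]]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3 || var(rank(a[ok])) == 0 || var(rank(b[ok])) == 0) {
        res$degenerate[i] <- TRUE
      } else {
        res$rho[i] <- spearman_rho(a[ok], b[ok])
      }
    }
    res$n_models <- nrow(cls)
    for (k in key_cols) res[[k]] <- cls[[k]][1]
    res
  })
  dplyr::bind_rows(out)[, c(key_cols, "metric_a", "metric_b", "rho",
                            "n_models", "degenerate")]
}
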