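#' Declare the column roles of a modelling dataset
#'
#' A validation dataset is an ordinary tibble whose columns have been
#' assigned roles: predictor columns, response columns, and optionally a
#' replicate-group column identifying repeated measurements of the same
#' sample. All downstream functions (fitting, cross-validation, resampling
#' sweeps) read these roles instead of taking separate matrices.
#'
#' @param data A data frame. All predictor and response columns must be
#'   numeric and free of missing values.
#' @param predictors Character vector of predictor column names.
#' @param responses Character vector of response column names (one for MLR,
#'   ANN and SVR models; one or more for PLS2).
#' @param group Optional name of a column holding replicate-group labels.
#'   Cases sharing a label are treated as repeated measurements of one
#'   sample and are never separated by a train/test split or a
#'   cross-validation fold.
#'
#' @return A tibble of class `validation_dataset` with the roles stored as
#'   attributes.
#' @examples
#' d <- data.frame(x1 = rnorm(20), x2 = rnorm(20), y = rnorm(20))
#' ds <- as_validation_dataset(d, predictors = c("x1", "x2"), responses = "y")
#' @export
as_validation_dataset <- function(data, predictors, responses, group = NULL) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(predictors, responses, group), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  num_cols <- c(predictors, responses)
  bad <- num_cols[!vapply(data[num_cols], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric predictor/response columns: ",
                 paste(bad, collapse = ", ")))
  }
  if (anyNA(data[num_cols])) {
    abort("predictor/response columns contain missing values")
  }
  if (nrow(data) < 2) abort("a validation dataset needs at least 2 cases")
  if (length(predictors) < 1) abort("at least one predictor column is required")
  if (length(responses) < 1) abort("at least one response column is required")
  new_validation_dataset(data, predictors, responses, group)
}

new_validation_dataset <- function(data, predictors, responses, group = NULL) {
  structure(
    tibble::as_tibble(data),
    predictors = predictors,
    responses = responses,
    group = group,
    class = c("validation_dataset", class(tibble::tibble()))
  )
}

#' @export
print.validation_dataset <- function(x, ...) {
  cat(sprintf(
    "<validation_dataset: %d cases, %d predictors, %d response%s%s>\n",
    nrow(x), length(attr(x, "predictors")), length(attr(x, "responses")),
    if (length(attr(x, "responses")) > 1) "s" else "",
    if (!is.null(attr(x, "group"))) ", grouped" else ""
  ))
  NextMethod()
}

# role accessors ------------------------------------------------------------

vd_predictors <- function(data) attr(data, "predictors")
vd_responses  <- function(data) attr(data, "responses")
vd_group_col  <- function(data) attr(data, "group")

vd_X <- function(data) {
  as.matrix(data[vd_predictors(data)])
}

vd_Y <- function(data) {
  as.matrix(data[vd_responses(data)])
}

# single response as a plain vector; errors when the dataset is multi-response
vd_y <- function(data) {
  resp <- vd_responses(data)
  if (length(resp) != 1) {
    abort("this operation needs a single-response dataset")
  }
  data[[resp]]
}

vd_groups <- function(data) {
  gc <- vd_group_col(data)
  if (is.null(gc)) NULL else data[[gc]]
}

# subset rows, keeping roles
vd_slice <- function(data, idx) {
  new_validation_dataset(
    as.data.frame(data)[idx, , drop = FALSE],
    vd_predictors(data), vd_responses(data), vd_group_col(data)
  )
}

assert_validation_dataset <- function(data) {
  if (!inherits(data, "validation_dataset")) {
    abort("`data` must be a validation_dataset; see as_validation_dataset()")
  }
  invisible(data)
}
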