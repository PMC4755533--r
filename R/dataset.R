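#' Construct a cohort dataset
#'
#' A `validisc_dataset` bundles a binary outcome vector with a numeric
#' predictor matrix. It is the unit on which prediction models are fitted
#' (development sample) and validated (external validation sample).
#'
#' @param outcomes Vector of binary outcome indicators (0/1), length `n`.
#' @param covariates Numeric matrix or data frame with `n` rows, one column
#'   per predictor. Column names are taken as predictor names unless
#'   `predictor_names` is supplied.
#' @param predictor_names Optional character vector of predictor labels,
#'   one per column of `covariates`.
#' @param sample_label Optional tag, conventionally `"development"` or
#'   `"validation"`.
#'
#' @details Missing values are rejected outright: silent row dropping would
#'   make development and validation cohorts incomparable. Outcomes must be
#'   coded 0/1 (logical vectors are coerced).
#'
#' @return An object of class `validisc_dataset` with elements `outcomes`
#'   (integer vector), `covariates` (numeric matrix with column names),
#'   `predictor_names`, and `sample_label`.
#' @seealso [read_dataset_csv()], [fit_logistic()]
#' @examples
#' d <- dataset(c(0, 1, 0, 1), matrix(c(0.1, 0.9, 0.2, 0.8), ncol = 1),
#'              predictor_names = "x")
#' d
#' @export
dataset <- function(outcomes, covariates, predictor_names = NULL,
                    sample_label = NULL) {
  if (is.logical(outcomes)) outcomes <- as.integer(outcomes)
  if (!is.numeric(outcomes)) {
    vd_error("non_binary_outcome", "outcomes must be numeric 0/1")
  }
  if (anyNA(outcomes)) {
    vd_error("missing_values", sprintf(
      "outcomes contain %d missing value(s)", sum(is.na(outcomes))
    ))
  }
  if (!all(outcomes %in% c(0, 1))) {
    bad <- unique(outcomes[!outcomes %in% c(0, 1)])
    vd_error("non_binary_outcome", sprintf(
      "outcomes must contain only 0 and 1; found: %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (is.vector(covariates)) covariates <- matrix(covariates, ncol = 1L)
  if (!is.matrix(covariates) || !is.numeric(covariates)) {
    vd_error("bad_argument", "covariates must be a numeric matrix")
  }
  if (nrow(covariates) != length(outcomes)) {
    vd_error("bad_argument", sprintf(
      "outcomes length (%d) does not match covariate rows (%d)",
      length(outcomes), nrow(covariates)
    ))
  }
  if (anyNA(covariates) || any(!is.finite(covariates))) {
    bad_rows <- which(apply(covariates, 1L, function(r) any(!is.finite(r))))
    vd_error("missing_values", sprintf(
      "covariates contain missing or non-finite values in %d row(s): %s",
      length(bad_rows),
      paste(utils::head(bad_rows, 10), collapse = ", ")
    ))
  }
  if (is.null(predictor_names)) {
    predictor_names <- colnames(covariates)
    if (is.null(predictor_names)) {
      predictor_names <- paste0("x", seq_len(ncol(covariates)))
    }
  }
  if (length(predictor_names) != ncol(covariates)) {
    vd_error("bad_argument", "predictor_names length must match covariate columns")
  }
  colnames(covariates) <- predictor_names
  structure(
    list(
      outcomes = as.integer(outcomes),
      covariates = covariates,
      predictor_names = as.character(predictor_names),
      sample_label = sample_label
    ),
    class = "validisc_dataset"
  )
}

#' @export
print.validisc_dataset <- function(x, ...) {
  lab <- if (is.null(x$sample_label)) "" else sprintf(" [%s]", x$sample_label)
  cat(sprintf(
    "<validisc_dataset%s> n = %d, events = %d (%.1f%%), predictors: %s\n",
    lab, length(x$outcomes), sum(x$outcomes),
    100 * mean(x$outcomes), paste(x$predictor_names, collapse = ", ")
  ))
  invisible(x)
}

#' Number of subjects in a dataset
#' @param x A `validisc_dataset`.
#' @return Integer row count.
#' @export
n_subjects <- function(x) {
  stopifnot(inherits(x, "validisc_dataset"))
  length(x$outcomes)
}

#' Specify a logistic model
#'
#' A model specification names the predictor columns to use and whether an
#' intercept is included. The same specification is applied to the
#' development sample (fitting) and the validation sample (refitting,
#' permutation rounds), which is what makes the benchmark comparisons
#' well defined.
#'
#' @param predictor_names Ordered character vector of predictor columns.
#' @param include_intercept Include an intercept term? Default `TRUE`.
#' @return An object of class `validisc_model_spec`.
#' @examples
#' model_spec("x")
#' @export
model_spec <- function(predictor_names, include_intercept = TRUE) {
  if (!is.character(predictor_names) || length(predictor_names) < 1L ||
      anyNA(predictor_names) || anyDuplicated(predictor_names) > 0L) {
    vd_error("bad_argument", "predictor_names must be distinct non-missing strings")
  }
  structure(
    list(
      predictor_names = predictor_names,
      include_intercept = isTRUE(include_intercept)
    ),
    class = "validisc_model_spec"
  )
}

#' @export
print.validisc_model_spec <- function(x, ...) {
  cat(sprintf(
    "<validisc_model_spec> logit(p) ~ %s%s\n",
    if (x$include_intercept) "1 + " else "",
    paste(x$predictor_names, collapse = " + ")
  ))
  invisible(x)
}

# Design matrix for a dataset under a spec; errors if columns are missing.
spec_design <- function(data, spec) {
  stopifnot(inherits(data, "validisc_dataset"))
  missing_cols <- setdiff(spec$predictor_names, data$predictor_names)
  if (length(missing_cols) > 0L) {
    vd_error("spec_mismatch", sprintf(
      "dataset lacks predictor column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  X <- data$covariates[, spec$predictor_names, drop = FALSE]
  if (spec$include_intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

# Default spec: all predictors of a dataset, with intercept.
default_spec <- function(data) model_spec(data$predictor_names)
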