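# I/O and orchestration: CSV loading, the one-call external validation
# report, and lossless JSON serialization of reports.

#' Read a cohort dataset from CSV
#'
#' Reads a CSV with a header row ("." decimal separator, UTF-8) and builds
#' a validated [dataset()]. Rows with missing values in the used columns
#' are rejected with an error naming how many rows are affected — never
#' silently dropped, since dropped rows would change the case-mix.
#'
#' @param path Path to the CSV file.
#' @param outcome_column Name of the binary outcome column.
#' @param predictor_columns Character vector of predictor column names.
#' @param sample_label Optional tag stored on the dataset.
#' @return A [dataset()].
#' @export
read_dataset_csv <- function(path, outcome_column, predictor_columns,
                             sample_label = NULL) {
  if (!file.exists(path)) {
    vd_error("missing_file", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- c(outcome_column, predictor_columns)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    vd_error("missing_columns", sprintf(
      "column(s) not in %s: %s", path, paste(missing_cols, collapse = ", ")
    ))
  }
  used <- df[, cols, drop = FALSE]
  bad <- which(!stats::complete.cases(used))
  if (length(bad) > 0L) {
    vd_error("missing_values", sprintf(
      "%d row(s) with missing values in used columns (rows %s); remove or impute before loading",
      length(bad), paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  dataset(
    outcomes = used[[outcome_column]],
    covariates = as.matrix(used[, predictor_columns, drop = FALSE]),
    predictor_names = predictor_columns,
    sample_label = sample_label
  )
}

#' Write a cohort dataset to CSV
#'
#' Writes the outcome column and predictor columns with full double
#' precision, so [read_dataset_csv()] recovers the dataset up to float
#' formatting (better than 1e-12 relative).
#'
#' @param data A [dataset()].
#' @param path Output CSV path.
#' @param outcome_column Name to give the outcome column. Default `"y"`.
#' @return Invisibly, `path`.
#' @export
write_dataset_csv <- function(data, path, outcome_column = "y") {
  stopifnot(inherits(data, "validisc_dataset"))
  if (outcome_column %in% data$predictor_names) {
    vd_error("bad_argument",
             "outcome_column collides with a predictor name")
  }
  df <- data.frame(data$outcomes, data$covariates, check.names = FALSE)
  names(df)[1L] <- outcome_column
  # default 15-significant-digit formatting: relative error ~1e-15
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full external-validation report
#'
#' One-call orchestration of the whole workflow: fits the model on the
#' development sample, computes the apparent development c-statistic and
#' the validation c-statistic, the linear-predictor SDs and their ratio,
#' the model-based c-statistic, the refitted c-statistic, and the
#' permutation test. The report carries the provenance (seed, `k`,
#' `n_reps`, `alpha`, fitted coefficients) needed to reproduce it.
#'
#' @param dev Development [dataset()].
#' @param val Validation [dataset()].
#' @param spec [model_spec()]; defaults to all predictors of `dev`.
#' @param k Permutation rounds (default 1000); `k = 0` skips the test.
#' @param n_reps mbc resimulation replicates per subject (default 100).
#' @param alpha Permutation rejection threshold (default 0.05).
#' @param seed Optional integer master seed for the mbc draws and the
#'   permutation rounds.
#' @param study_label Free-text label stored in the report.
#' @return An object of class `validisc_report`.
#' @examples
#' set.seed(3)
#' x <- rnorm(80); xv <- rnorm(80)
#' dev <- dataset(rbinom(80, 1, plogis(2 * x)), cbind(x = x))
#' val <- dataset(rbinom(80, 1, plogis(2 * xv)), cbind(x = xv))
#' validate_external(dev, val, k = 100, seed = 1)
#' @export
validate_external <- function(dev, val, spec = default_spec(dev),
                              k = 1000L, n_reps = 100L, alpha = 0.05,
                              seed = NULL, study_label = "") {
  seeds <- spawn_seeds(2L, seed)
  model <- fit_logistic(dev, spec)
  cm <- casemix_summary(model, dev, val)
  c_dev <- c_statistic(linear_predictor(model, dev), dev$outcomes)
  c_val <- c_statistic(linear_predictor(model, val), val$outcomes)
  mbc <- model_based_c(model, val, n_reps = n_reps, seed = seeds[1L])
  c_refit <- refitted_c(val, spec)
  if (k > 0L) {
    pt <- permutation_test(dev, val, spec, k = k, alpha = alpha,
                           seed = seeds[2L])
    perm_p <- pt$p_value
    reject <- pt$reject
  } else {
    perm_p <- NA_real_
    reject <- NA
  }
  structure(
    list(
      study_label = study_label,
      c_dev = c_dev,
      c_val = c_val,
      sd_lp_dev = cm$sd_lp_dev,
      sd_lp_val = cm$sd_lp_val,
      ratio = cm$ratio,
      mbc = mbc,
      c_refitted = c_refit,
      perm_p = perm_p,
      reject = reject,
      k = as.integer(k),
      n_reps = as.integer(n_reps),
      alpha = alpha,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      intercept = model$intercept,
      coefficients = model$coefficients,
      converged = model$converged
    ),
    class = "validisc_report"
  )
}

#' @export
print.validisc_report <- function(x, digits = 2, ...) {
  cat(sprintf("<validisc_report> %s\n",
              if (nzchar(x$study_label)) x$study_label else "(unlabeled)"))
  cat(sprintf("  c (development, apparent)   %.*f\n", digits, x$c_dev))
  cat(sprintf("  c (external validation)     %.*f\n", digits, x$c_val))
  cat(sprintf("  SD lp (dev) / (val) / ratio %.*f / %.*f / %.*f\n",
              digits, x$sd_lp_dev, digits, x$sd_lp_val, digits, x$ratio))
  cat(sprintf("  mbc (case-mix benchmark)    %.*f\n", digits, x$mbc))
  cat(sprintf("  c (refitted upper bound)    %.*f\n", digits, x$c_refitted))
  if (!is.na(x$perm_p)) {
    cat(sprintf("  permutation p (k = %d)     %.*f [%s]\n", x$k, digits,
                x$perm_p,
                if (isTRUE(x$reject)) "reject homogeneity" else "no rejection"))
  }
  invisible(x)
}

#' Serialize / restore a validation report
#'
#' JSON round-trip is lossless: numeric fields are written at full double
#' precision and restored bitwise.
#'
#' @param report A `validisc_report`.
#' @param path Output / input JSON path.
#' @return `write_validation_report` invisibly returns `path`;
#'   `read_validation_report` returns the restored `validisc_report`.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validisc_report"))
  payload <- unclass(report)
  payload$coefficients <- as.list(payload$coefficients)
  # 17 significant digits: doubles survive the round trip bitwise
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  if (!file.exists(path)) {
    vd_error("missing_file", sprintf("file not found: %s", path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- unlist(x$coefficients)
  x$perm_p <- if (is.null(x$perm_p)) NA_real_ else x$perm_p
  x$reject <- if (is.null(x$reject)) NA else x$reject
  x$seed <- if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  x$k <- as.integer(x$k)
  x$n_reps <- as.integer(x$n_reps)
  structure(x[c("study_label", "c_dev", "c_val", "sd_lp_dev", "sd_lp_val",
                "ratio", "mbc", "c_refitted", "perm_p", "reject", "k",
                "n_reps", "alpha", "seed", "intercept", "coefficients",
                "converged")],
            class = "validisc_report")
}
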