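# Concordance statistic and case-mix measures.

# Rank-based c-statistic without argument checking, for hot loops.
# Midranks give tied pairs half credit, matching the Mann-Whitney AUC.
c_stat_fast <- function(scores, outcomes) {
  r <- rank(scores)
  n1 <- as.numeric(sum(outcomes))  # numeric: n1 * n0 overflows int range
  n0 <- length(outcomes) - n1
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance (c-) statistic
#'
#' The probability that, for a randomly chosen event/non-event pair, the
#' event subject has the higher score; tied scores count one half. For
#' binary outcomes this equals the area under the ROC curve, and is
#' computed here from midranks (Mann-Whitney form) in O(n log n).
#'
#' @param scores Numeric vector of risk scores (any monotone transform of
#'   predicted risk gives the same value).
#' @param outcomes Binary 0/1 vector of the same length, with at least one
#'   event and one non-event.
#' @return A number in \[0, 1\].
#' @examples
#' c_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1)) # 1: perfect separation
#' @export
c_statistic <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) {
    vd_error("bad_argument", "scores and outcomes must have equal length")
  }
  if (anyNA(scores) || anyNA(outcomes)) {
    vd_error("missing_values", "scores and outcomes must not contain NA")
  }
  if (!all(outcomes %in% c(0, 1))) {
    vd_error("non_binary_outcome", "outcomes must contain only 0 and 1")
  }
  n1 <- sum(outcomes)
  if (n1 == 0L || n1 == length(outcomes)) {
    vd_error("undefined_c_statistic",
             "c-statistic undefined: need at least one event and one non-event")
  }
  c_stat_fast(scores, as.integer(outcomes))
}

#' Standard deviation of a linear predictor
#'
#' The sample SD (denominator n - 1) of the linear predictor is the scalar
#' case-mix heterogeneity measure used throughout this package: a more
#' heterogeneous population has a wider linear-predictor distribution.
#'
#' @param lp Numeric vector of length >= 2.
#' @return Nonnegative number.
#' @export
sd_linear_predictor <- function(lp) {
  if (!is.numeric(lp) || length(lp) < 2L) {
    vd_error("bad_argument", "lp must be a numeric vector of length >= 2")
  }
  if (anyNA(lp)) vd_error("missing_values", "lp must not contain NA")
  stats::sd(lp)
}

#' Case-mix comparison between development and validation samples
#'
#' Computes the SD of the linear predictor in the development sample
#' (`sd_lp_dev`) and in the validation sample (`sd_lp_val`), both under the
#' DEVELOPMENT model's coefficients, and their ratio
#' (validation / development). A ratio above 1 indicates a more
#' heterogeneous validation case-mix; below 1, a less heterogeneous one.
#' Intercept shifts do not affect any of the three quantities.
#'
#' @param model A `validisc_fit` fitted on the development sample.
#' @param dev Development [dataset()].
#' @param val Validation [dataset()].
#' @return An object of class `validisc_casemix` with fields `sd_lp_dev`,
#'   `sd_lp_val`, `ratio`.
#' @export
casemix_summary <- function(model, dev, val) {
  sd_dev <- sd_linear_predictor(linear_predictor(model, dev))
  sd_val <- sd_linear_predictor(linear_predictor(model, val))
  if (sd_dev == 0) {
    vd_warning("degenerate_casemix",
               "development linear predictor is constant; ratio undefined")
    ratio <- NaN
  } else {
    ratio <- sd_val / sd_dev
  }
  structure(
    list(sd_lp_dev = sd_dev, sd_lp_val = sd_val, ratio = ratio),
    class = "validisc_casemix"
  )
}

#' @export
print.validisc_casemix <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<validisc_casemix> SD lp (dev) = %.*f, SD lp (val) = %.*f, ratio = %.*f\n",
    digits, x$sd_lp_dev, digits, x$sd_lp_val, digits, x$ratio
  ))
  invisible(x)
}
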