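# Logistic-regression core: a lean iteratively reweighted least squares
# fitter with a tiny ridge penalty on the slopes. The permutation test
# refits the model hundreds of thousands of times in a simulation run, so
# the fitter operates directly on design matrices and avoids the overhead
# of model formulas.

# Fit on a raw design matrix. `penalty` is per-coefficient (0 for the
# intercept). Convergence on either the Newton step or the relative
# deviance change; under (quasi-)separation the deviance plateaus while
# the coefficients drift, so the deviance criterion terminates those fits
# once the ranking of the linear predictor is stable.
irls_fit <- function(X, y, penalty, maxit = 100L, tol = 1e-8) {
  beta <- numeric(ncol(X))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    g <- drop(crossprod(X, y - mu)) - penalty * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + penalty
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      vd_error("collinear_predictors",
               "singular information matrix: collinear predictors")
    }
    beta <- beta + step
    eta <- drop(X %*% beta)
    dev <- -2 * sum(ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
                           stats::plogis(-eta, log.p = TRUE)))
    if (max(abs(step)) < tol || abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  list(beta = beta, converged = converged, iterations = it)
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, with a tiny ridge penalty (`ridge`, default `1e-6`) on the
#' slope coefficients only — never on the intercept. The penalty leaves
#' ordinary estimates unchanged to well below reporting precision but keeps
#' the fit finite under the complete or quasi-complete separation that
#' occasionally occurs in small samples with strong predictors. All
#' downstream measures in this package (c-statistics, linear-predictor
#' spread, benchmarks) are rank- or spread-based and insensitive to this
#' stabilization.
#'
#' @param data A [dataset()] with at least one event and one non-event.
#' @param spec A [model_spec()]; defaults to all predictors with intercept.
#' @param ridge L2 penalty applied to slopes. Default `1e-6`.
#' @param maxit Maximum IRLS iterations. Default 100; the fit is flagged
#'   `converged = FALSE` if neither the step-size nor the deviance
#'   criterion is met within the cap.
#' @return An object of class `validisc_fit` with elements `intercept`,
#'   `coefficients` (named, aligned to `spec$predictor_names`),
#'   `predictor_names`, `include_intercept`, `converged`, and `n_used`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' d <- dataset(rbinom(200, 1, plogis(2 * x)), cbind(x = x))
#' fit_logistic(d)
#' @export
fit_logistic <- function(data, spec = default_spec(data), ridge = 1e-6,
                         maxit = 100L) {
  stopifnot(inherits(data, "validisc_dataset"))
  y <- data$outcomes
  n <- length(y)
  n_events <- sum(y)
  if (n_events == 0L || n_events == n) {
    vd_error("degenerate_outcome",
             "cannot fit: outcomes are all 0 or all 1")
  }
  X <- spec_design(data, spec)
  if (ncol(X) >= n) {
    vd_error("bad_argument", sprintf(
      "need more observations (%d) than parameters (%d)", n, ncol(X)
    ))
  }
  if (qr(X)$rank < ncol(X)) {
    vd_error("collinear_predictors",
             "collinear predictors: design matrix is rank deficient")
  }
  penalty <- rep(ridge, ncol(X))
  if (spec$include_intercept) penalty[1L] <- 0
  fit <- irls_fit(X, y, penalty, maxit = maxit)
  if (any(!is.finite(fit$beta))) {
    vd_error("fit_failed", "fitting produced non-finite coefficients")
  }
  p <- length(spec$predictor_names)
  coefs <- fit$beta[(ncol(X) - p + 1L):ncol(X)]
  names(coefs) <- spec$predictor_names
  structure(
    list(
      intercept = if (spec$include_intercept) unname(fit$beta[1L]) else 0,
      coefficients = coefs,
      predictor_names = spec$predictor_names,
      include_intercept = spec$include_intercept,
      converged = fit$converged,
      n_used = n
    ),
    class = "validisc_fit"
  )
}

#' @export
print.validisc_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<validisc_fit> logistic model, n = %d%s\n", x$n_used,
              if (x$converged) "" else " (NOT converged)"))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), digits))
  invisible(x)
}

#' Linear predictor of a fitted model on a dataset
#'
#' Computes `intercept + X %*% coefficients` for every subject. Applying a
#' development-fitted model to validation covariates yields the validation
#' linear predictor whose spread measures validation case-mix under the
#' development model.
#'
#' @param model A `validisc_fit`.
#' @param data A [dataset()] containing the model's predictor columns.
#' @return Numeric vector of length `n_subjects(data)`.
#' @export
linear_predictor <- function(model, data) {
  stopifnot(inherits(model, "validisc_fit"))
  missing_cols <- setdiff(model$predictor_names, data$predictor_names)
  if (length(missing_cols) > 0L) {
    vd_error("spec_mismatch", sprintf(
      "dataset lacks predictor column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  drop(data$covariates[, model$predictor_names, drop = FALSE] %*%
         model$coefficients) + model$intercept
}

#' Predicted event probabilities
#'
#' Element-wise inverse logit of [linear_predictor()]. Values are finite
#' and lie strictly inside (0, 1) up to double precision saturation.
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of probabilities.
#' @export
predict_probability <- function(model, data) {
  p <- stats::plogis(linear_predictor(model, data))
  # keep strictly inside (0,1) even where plogis saturates
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}
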