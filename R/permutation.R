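# Permutation test of development/validation homogeneity based on the
# change in c-statistic.

#' Permutation test of development/validation homogeneity
#'
#' Tests the null hypothesis that the development and validation samples
#' come from one homogeneous population, using the c-statistic at external
#' validation as the test statistic. The observed statistic `c_observed`
#' is the c-statistic on the validation sample of a model fitted on the
#' development sample. In each of `k` rounds all subjects are pooled and
#' randomly reassigned to a permuted development set of the original size
#' `n_dev` and a permuted validation set of size `n_val`; the model
#' specification is refitted on the permuted development set and its
#' c-statistic computed on the permuted validation set. The p-value is the
#' proportion of rounds in which the permuted c-statistic lies strictly
#' below `c_observed` (one-sided, no smoothing: with `k` rounds the
#' attainable p-values include exactly 0 and 1).
#'
#' Rounds whose permuted development set has all-0 or all-1 outcomes (or
#' an otherwise unfittable model) are redrawn, never dropped; dropping
#' them would bias the p-value. A warning is raised if more than 1% of
#' rounds needed a redraw.
#'
#' @param dev Development [dataset()].
#' @param val Validation [dataset()].
#' @param spec [model_spec()] shared by both samples; defaults to all
#'   predictors of `dev`.
#' @param k Number of permutation rounds (default 1000).
#' @param alpha Rejection threshold on the p-value (default 0.05).
#' @param seed Optional integer seed; identical seeds give identical
#'   permuted c-statistic vectors.
#' @return An object of class `validisc_permutation` with fields
#'   `c_observed`, `permuted_c` (length `k`), `p_value`, `k`, `alpha`,
#'   `reject`, `n_redraws`, `seed`.
#' @examples
#' set.seed(7)
#' x <- rnorm(60)
#' dev <- dataset(rbinom(60, 1, plogis(2 * x)), cbind(x = x))
#' xv <- rnorm(60)
#' val <- dataset(rbinom(60, 1, plogis(2 * xv)), cbind(x = xv))
#' permutation_test(dev, val, k = 200, seed = 1)
#' @export
permutation_test <- function(dev, val, spec = default_spec(dev), k = 1000L,
                             alpha = 0.05, seed = NULL) {
  k <- check_count(k, "k", min = 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    vd_error("bad_argument", "alpha must be in (0, 1)")
  }
  model <- fit_logistic(dev, spec)
  c_obs <- c_statistic(linear_predictor(model, val), val$outcomes)

  X_pool <- rbind(spec_design(dev, spec), spec_design(val, spec))
  y_pool <- c(dev$outcomes, val$outcomes)
  n <- length(y_pool)
  n_dev <- length(dev$outcomes)
  s_pool <- sum(y_pool)
  if (s_pool == 0L || s_pool == n) {
    vd_error("degenerate_outcome",
             "pooled outcomes are all 0 or all 1; permutation test undefined")
  }
  penalty <- rep(1e-6, ncol(X_pool))
  if (spec$include_intercept) penalty[1L] <- 0

  run <- function() {
    permuted_c <- numeric(k)
    redraws <- 0L
    for (r in seq_len(k)) {
      repeat {
        idx <- sample.int(n, n_dev)
        y_d <- y_pool[idx]
        s <- sum(y_d)
        if (s > 0L && s < n_dev) {
          fit <- tryCatch(
            irls_fit(X_pool[idx, , drop = FALSE], y_d, penalty),
            error = function(e) NULL
          )
          if (!is.null(fit) && all(is.finite(fit$beta))) break
        }
        redraws <- redraws + 1L
        if (redraws > 100L * k) {
          vd_error("degenerate_outcome",
                   "could not draw a fittable permuted development set")
        }
      }
      lp_v <- drop(X_pool[-idx, , drop = FALSE] %*% fit$beta)
      permuted_c[r] <- c_stat_fast(lp_v, y_pool[-idx])
    }
    list(permuted_c = permuted_c, redraws = redraws)
  }
  res <- with_seed(seed, run())
  if (res$redraws > 0.01 * k) {
    vd_warning("many_redraws", sprintf(
      "%d of %d permutation rounds required redraws", res$redraws, k
    ))
  }
  p_value <- sum(res$permuted_c < c_obs) / k
  structure(
    list(
      c_observed = c_obs,
      permuted_c = res$permuted_c,
      p_value = p_value,
      k = k,
      alpha = alpha,
      reject = p_value < alpha,
      n_redraws = res$redraws,
      seed = seed
    ),
    class = "validisc_permutation"
  )
}

#' @export
print.validisc_permutation <- function(x, digits = 3, ...) {
  cat(sprintf(
    paste0("<validisc_permutation> c_observed = %.*f, k = %d, ",
           "p = %.*f (%sreject homogeneity at alpha = %g)\n"),
    digits, x$c_observed, x$k, digits, x$p_value,
    if (x$reject) "" else "do not ", x$alpha
  ))
  invisible(x)
}

#' Rejection rate over a collection of permutation tests
#'
#' @param results A list of `validisc_permutation` objects sharing a
#'   common `alpha`.
#' @return Fraction of tests that rejected homogeneity, in \[0, 1\].
#' @export
rejection_rate <- function(results) {
  if (!is.list(results) || length(results) == 0L) {
    vd_error("bad_argument", "results must be a nonempty list")
  }
  ok <- vapply(results, inherits, logical(1), "validisc_permutation")
  if (!all(ok)) {
    vd_error("bad_argument", "results must all be validisc_permutation objects")
  }
  alphas <- vapply(results, `[[`, numeric(1), "alpha")
  if (length(unique(alphas)) != 1L) {
    vd_error("bad_argument", "all results must share one alpha")
  }
  mean(vapply(results, `[[`, logical(1), "reject"))
}
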