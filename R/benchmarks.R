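# Benchmark c-statistics: the model-based c-statistic (mbc) and the
# refitted c-statistic. Together they decompose the observed validation
# c-statistic into a case-mix component and a coefficient-validity
# component: mbc is what the model WOULD achieve in the validation
# case-mix if its predictions were exactly correct; the refitted
# c-statistic is the upper bound achievable in that case-mix by the same
# model specification with the best (locally re-estimated) coefficients.

#' Model-based c-statistic (mbc)
#'
#' The expected c-statistic in the validation population under the
#' assumption that the model's predicted probabilities are correct.
#' Estimated by outcome resimulation: each validation subject is
#' replicated `n_reps` times, a synthetic outcome is drawn from
#' Bernoulli(p_i) for each replicate, and one pooled c-statistic of the
#' replicated predicted probabilities against the synthetic outcomes is
#' returned. A gap between mbc and the observed validation c-statistic
#' signals incorrect coefficients; case-mix differences alone move both
#' together.
#'
#' @param model A `validisc_fit` (normally fitted on the development
#'   sample).
#' @param val Validation [dataset()].
#' @param n_reps Outcome-resimulation replicates per subject; at least 100
#'   are required for a stable estimate. Default 100.
#' @param seed Optional integer seed for the resimulation draws.
#' @return A number in \[0, 1\].
#' @examples
#' set.seed(42)
#' x <- rnorm(100)
#' d <- dataset(rbinom(100, 1, plogis(2 * x)), cbind(x = x))
#' m <- fit_logistic(d)
#' model_based_c(m, d, n_reps = 200, seed = 1)
#' @export
model_based_c <- function(model, val, n_reps = 100L, seed = NULL) {
  n_reps <- check_count(n_reps, "n_reps", min = 100L)
  p <- predict_probability(model, val)
  pr <- rep.int(p, n_reps)
  sims <- with_seed(seed, stats::rbinom(length(pr), 1L, pr))
  s <- sum(sims)
  if (s == 0L || s == length(sims)) {
    vd_error("degenerate_outcome",
             "all simulated outcomes identical; mbc undefined")
  }
  c_stat_fast(pr, sims)
}

#' Refitted c-statistic
#'
#' Re-estimates the same model specification on the validation sample and
#' returns the apparent c-statistic of that refit on the same data. This
#' is the discrimination the model class can achieve in the validation
#' case-mix, an upper bound used to judge coefficient validity. For a
#' single-predictor model whose refit slope has the same sign as the
#' original slope, the refitted c-statistic equals the observed validation
#' c-statistic exactly (the c-statistic is rank based).
#'
#' @param val Validation [dataset()].
#' @param spec A [model_spec()]; defaults to all predictors of `val`.
#' @return A number in \[0, 1\].
#' @export
refitted_c <- function(val, spec = default_spec(val)) {
  refit <- fit_logistic(val, spec)
  c_statistic(linear_predictor(refit, val), val$outcomes)
}
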