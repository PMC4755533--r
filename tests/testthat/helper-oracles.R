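# Independent oracles and small data helpers used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) pairwise concordance: every event/non-event pair scored 1 / 0.5 / 0.
c_stat_pairwise <- function(scores, outcomes) {
  ev <- scores[outcomes == 1]
  ne <- scores[outcomes == 0]
  total <- 0
  for (a in ev) for (b in ne) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(ev) * length(ne))
}

# One logistic sample: x ~ N(0, sigma^2), y ~ Bern(plogis(beta * x)).
make_logistic_data <- function(n, beta, sigma = 1, label = NULL) {
  x <- rnorm(n, 0, sigma)
  dataset(rbinom(n, 1, plogis(beta * x)), cbind(x = x), sample_label = label)
}

# A fitted-model object with known intercept/slopes, for oracle checks
# that need exact coefficients rather than estimates.
manual_fit <- function(intercept, coefficients) {
  structure(
    list(
      intercept = intercept,
      coefficients = coefficients,
      predictor_names = names(coefficients),
      include_intercept = TRUE,
      converged = TRUE,
      n_used = NA_integer_
    ),
    class = "validisc_fit"
  )
}
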