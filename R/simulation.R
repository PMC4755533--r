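# Simulation engine: scenario data generation, per-replicate evaluation,
# and study-level summaries.
#
# The data-generating model is a single-predictor logistic model without
# intercept: x ~ N(0, sigma^2), y ~ Bernoulli(plogis(beta * x)), with
# separate (sigma, beta) for the development and validation populations.
# Varying sigma_val against sigma_dev changes the validation case-mix
# heterogeneity; varying beta_val against beta_dev makes the development
# coefficients invalid in the validation population.

#' Define a simulation scenario
#'
#' @param sigma_dev,sigma_val SD of the predictor in the development /
#'   validation population (strictly positive).
#' @param beta_dev,beta_val True predictor coefficient in the development /
#'   validation population.
#' @param n_dev,n_val Sample sizes (>= 10 each).
#' @param label Free-text scenario label.
#' @return An object of class `validisc_scenario`.
#' @examples
#' scenario_config(1, 1.5, 3, 2, 40, 40, "heterogeneous case-mix, weaker effects")
#' @export
scenario_config <- function(sigma_dev, sigma_val, beta_dev, beta_val,
                            n_dev, n_val, label = "") {
  if (!is.numeric(sigma_dev) || sigma_dev <= 0 ||
      !is.numeric(sigma_val) || sigma_val <= 0) {
    vd_error("bad_argument", "sigma_dev and sigma_val must be > 0")
  }
  n_dev <- check_count(n_dev, "n_dev", min = 10L)
  n_val <- check_count(n_val, "n_val", min = 10L)
  structure(
    list(
      sigma_dev = as.numeric(sigma_dev), sigma_val = as.numeric(sigma_val),
      beta_dev = as.numeric(beta_dev), beta_val = as.numeric(beta_val),
      n_dev = n_dev, n_val = n_val, label = as.character(label)
    ),
    class = "validisc_scenario"
  )
}

#' @export
print.validisc_scenario <- function(x, ...) {
  cat(sprintf(
    "<validisc_scenario> %s: sigma = (%g, %g), beta = (%g, %g), n = (%d, %d)\n",
    if (nzchar(x$label)) x$label else "(unlabeled)",
    x$sigma_dev, x$sigma_val, x$beta_dev, x$beta_val, x$n_dev, x$n_val
  ))
  invisible(x)
}

#' The canonical three-scenario grid
#'
#' The three case-mix / coefficient-validity scenarios crossed with sample
#' sizes 40, 100 and 200 per set (nine configurations):
#' \describe{
#'   \item{homogeneous}{sigma_val = sigma_dev = 1, beta_val = beta_dev = 3:
#'     validation population identical to development.}
#'   \item{heterogeneous-weaker}{sigma_val = 1.5, beta_val = 2: more
#'     heterogeneous validation case-mix AND weaker predictor effects.}
#'   \item{homogeneous-narrower}{sigma_val = 0.75, beta_val = 3: less
#'     heterogeneous validation case-mix, identical predictor effects.}
#' }
#'
#' @param sample_sizes Integer vector of per-set sample sizes to cross
#'   with the three scenario rows. Default `c(40, 100, 200)`.
#' @return A list of [scenario_config()] objects (by default of length 9).
#' @export
scenario_grid <- function(sample_sizes = c(40L, 100L, 200L)) {
  rows <- list(
    list(sigma_val = 1.00, beta_val = 3, label = "Homogeneous populations"),
    list(sigma_val = 1.50, beta_val = 2, label = "Different case-mix & predictor effects"),
    list(sigma_val = 0.75, beta_val = 3, label = "Different case-mix & same predictor effects")
  )
  configs <- list()
  for (row in rows) {
    for (n in sample_sizes) {
      configs[[length(configs) + 1L]] <- scenario_config(
        sigma_dev = 1, sigma_val = row$sigma_val,
        beta_dev = 3, beta_val = row$beta_val,
        n_dev = n, n_val = n, label = row$label
      )
    }
  }
  configs
}

# Generate one sample from a (sigma, beta, n) population.
generate_sample <- function(sigma, beta, n, sample_label) {
  x <- stats::rnorm(n, 0, sigma)
  y <- stats::rbinom(n, 1L, stats::plogis(beta * x))
  dataset(y, cbind(x = x), sample_label = sample_label)
}

#' Generate a development/validation pair under a scenario
#'
#' Draws independent development and validation samples from the scenario's
#' populations. No degeneracy handling is applied here; see
#' [run_replicate()] for the redraw rule used inside studies.
#'
#' @param config A [scenario_config()].
#' @param seed Optional integer seed.
#' @return A list with elements `dev` and `val`, both [dataset()]s.
#' @export
generate_scenario_pair <- function(config, seed = NULL) {
  stopifnot(inherits(config, "validisc_scenario"))
  with_seed(seed, {
    dev <- generate_sample(config$sigma_dev, config$beta_dev, config$n_dev,
                           "development")
    val <- generate_sample(config$sigma_val, config$beta_val, config$n_val,
                           "validation")
    list(dev = dev, val = val)
  })
}

fittable <- function(d) {
  s <- sum(d$outcomes)
  s > 0L && s < length(d$outcomes)
}

#' Run one simulation replicate
#'
#' Generates a development/validation pair, fits the single-predictor
#' logistic model on the development sample, and computes the full set of
#' validation measures: apparent development c-statistic (`c_dev`),
#' validation c-statistic (`c_val`), linear-predictor SDs and their ratio,
#' the model-based c-statistic (`mbc`), the refitted c-statistic
#' (`c_refitted`), and optionally the permutation test. Pairs in which
#' either sample has all-0 or all-1 outcomes are redrawn whole (counted in
#' `n_pair_redraws`) so that every replicate contributes.
#'
#' @param config A [scenario_config()].
#' @param k Permutation rounds (used when `with_permutation = TRUE`).
#' @param with_permutation Run the permutation test? Default `TRUE`.
#' @param n_reps Outcome-resimulation replicates per subject for the mbc.
#' @param alpha Permutation rejection threshold.
#' @param seed Optional integer seed; a fixed seed makes the replicate
#'   bitwise reproducible.
#' @return An object of class `validisc_replicate`: a list of the metrics
#'   above plus `perm_p`, `reject` (NA when the test is skipped),
#'   `n_pair_redraws`, `converged` and `seed`.
#' @export
run_replicate <- function(config, k = 1000L, with_permutation = TRUE,
                          n_reps = 100L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(config, "validisc_scenario"))
  with_seed(seed, {
    redraws <- 0L
    repeat {
      pair <- list(
        dev = generate_sample(config$sigma_dev, config$beta_dev,
                              config$n_dev, "development"),
        val = generate_sample(config$sigma_val, config$beta_val,
                              config$n_val, "validation")
      )
      if (fittable(pair$dev) && fittable(pair$val)) break
      redraws <- redraws + 1L
      if (redraws > 1000L) {
        vd_error("degenerate_outcome",
                 "could not generate a fittable development/validation pair")
      }
    }
    spec <- model_spec("x")
    model <- fit_logistic(pair$dev, spec)
    lp_dev <- linear_predictor(model, pair$dev)
    lp_val <- linear_predictor(model, pair$val)
    cm <- casemix_summary(model, pair$dev, pair$val)
    res <- list(
      c_dev = c_statistic(lp_dev, pair$dev$outcomes),
      c_val = c_statistic(lp_val, pair$val$outcomes),
      sd_lp_dev = cm$sd_lp_dev,
      sd_lp_val = cm$sd_lp_val,
      ratio = cm$ratio,
      mbc = model_based_c(model, pair$val, n_reps = n_reps),
      c_refitted = refitted_c(pair$val, spec),
      perm_p = NA_real_,
      reject = NA,
      n_pair_redraws = redraws,
      converged = model$converged,
      seed = seed
    )
    if (with_permutation) {
      pt <- permutation_test(pair$dev, pair$val, spec, k = k, alpha = alpha)
      res$perm_p <- pt$p_value
      res$reject <- pt$reject
    }
    structure(res, class = "validisc_replicate")
  })
}

replicate_metrics <- c("c_dev", "c_val", "sd_lp_dev", "sd_lp_val",
                       "ratio", "mbc", "c_refitted")

#' Run a full simulation study for one scenario
#'
#' Runs `n_replicates` independent replicates (each with its own sub-seed
#' spawned from `seed`, so any replicate can be reproduced in isolation)
#' and summarizes every metric by its median and interquartile range, plus
#' the proportion of replicates in which the permutation test rejected
#' homogeneity.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates (>= 2).
#' @param replicate_seeds Optional integer vector of length `n_replicates`
#'   overriding the spawned sub-seeds.
#' @return An object of class `validisc_study`: `config`, `n_replicates`,
#'   `k`, `n_reps`, `alpha`, `metrics` (data frame with columns `metric`,
#'   `median`, `q25`, `q75`), `rejection_proportion` (NA without
#'   permutation), `replicates` (data frame of per-replicate values) and
#'   `n_pair_redraws`.
#' @export
run_study <- function(config, n_replicates = 1000L, k = 1000L,
                      with_permutation = TRUE, n_reps = 100L, alpha = 0.05,
                      seed = NULL, replicate_seeds = NULL) {
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  if (is.null(replicate_seeds)) {
    replicate_seeds <- spawn_seeds(n_replicates, seed)
  } else if (length(replicate_seeds) != n_replicates) {
    vd_error("bad_argument",
             "replicate_seeds must have length n_replicates")
  }
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reps[[r]] <- run_replicate(config, k = k,
                               with_permutation = with_permutation,
                               n_reps = n_reps, alpha = alpha,
                               seed = replicate_seeds[r])
  }
  rep_df <- do.call(rbind, lapply(reps, function(x) {
    data.frame(x[c(replicate_metrics, "perm_p", "reject",
                   "n_pair_redraws")])
  }))
  metrics <- do.call(rbind, lapply(replicate_metrics, function(m) {
    q <- stats::quantile(rep_df[[m]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(metric = m, median = q[2], q25 = q[1], q75 = q[3])
  }))
  structure(
    list(
      config = config,
      n_replicates = n_replicates,
      k = if (with_permutation) as.integer(k) else NA_integer_,
      n_reps = as.integer(n_reps),
      alpha = alpha,
      metrics = metrics,
      rejection_proportion = if (with_permutation) mean(rep_df$reject)
                             else NA_real_,
      replicates = rep_df,
      n_pair_redraws = sum(rep_df$n_pair_redraws)
    ),
    class = "validisc_study"
  )
}

#' @export
print.validisc_study <- function(x, digits = 2, ...) {
  cat(sprintf("<validisc_study> %s (n_dev = %d, n_val = %d), %d replicates\n",
              x$config$label, x$config$n_dev, x$config$n_val, x$n_replicates))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-10s %.*f (%.*f-%.*f)\n", m$metric[i],
                digits, m$median[i], digits, m$q25[i], digits, m$q75[i]))
  }
  if (!is.na(x$rejection_proportion)) {
    cat(sprintf("  rejection proportion (alpha = %g, k = %d): %.2f\n",
                x$alpha, x$k, x$rejection_proportion))
  }
  invisible(x)
}

#' Tidy one study or a list of studies
#'
#' @param studies A `validisc_study` or list of them.
#' @return A tidy data frame, one row per scenario x metric, with columns
#'   `label`, `n_dev`, `n_val`, `metric`, `median`, `q25`, `q75`, plus one
#'   `rejection_proportion` row per study when the permutation test ran.
#' @export
tidy_studies <- function(studies) {
  if (inherits(studies, "validisc_study")) studies <- list(studies)
  do.call(rbind, lapply(studies, function(s) {
    base <- data.frame(
      label = s$config$label, n_dev = s$config$n_dev, n_val = s$config$n_val
    )
    out <- cbind(base[rep(1L, nrow(s$metrics)), , drop = FALSE], s$metrics)
    if (!is.na(s$rejection_proportion)) {
      out <- rbind(out, cbind(base, data.frame(
        metric = "rejection_proportion",
        median = s$rejection_proportion, q25 = NA_real_, q75 = NA_real_
      )))
    }
    rownames(out) <- NULL
    out
  }))
}

#' Write study summaries to tidy CSV and JSON
#'
#' @param studies A `validisc_study` or list of them.
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return Invisibly, the tidy data frame written.
#' @export
write_studies <- function(studies, csv_path = NULL, json_path = NULL) {
  df <- tidy_studies(studies)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    if (inherits(studies, "validisc_study")) studies <- list(studies)
    payload <- lapply(studies, function(s) {
      list(
        label = s$config$label,
        config = unclass(s$config),
        n_replicates = s$n_replicates,
        k = s$k, n_reps = s$n_reps, alpha = s$alpha,
        metrics = s$metrics,
        rejection_proportion = s$rejection_proportion,
        n_pair_redraws = s$n_pair_redraws
      )
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(df)
}
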