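toy_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("CSV loading validates outcomes, columns and missingness", {
  path <- toy_csv(data.frame(y = c(0, 1, 0, 1), x = c(0.1, 0.9, 0.2, 0.8)))
  d <- read_dataset_csv(path, "y", "x")
  expect_s3_class(d, "validisc_dataset")
  expect_equal(n_subjects(d), 4)
  expect_equal(d$predictor_names, "x")

  expect_error(read_dataset_csv(tempfile(), "y", "x"),
               class = "validisc_error_missing_file")
  expect_error(read_dataset_csv(path, "y", c("x", "zz")),
               class = "validisc_error_missing_columns")

  bad_y <- toy_csv(data.frame(y = c(0, 1, 2, 1), x = 1:4))
  expect_error(read_dataset_csv(bad_y, "y", "x"),
               class = "validisc_error_non_binary_outcome")

  holey <- toy_csv(data.frame(y = c(0, 1, 0), x = c(0.1, NA, 0.3)))
  err <- tryCatch(read_dataset_csv(holey, "y", "x"), error = identity)
  expect_s3_class(err, "validisc_error_missing_values")
  expect_match(conditionMessage(err), "1 row")
  expect_match(conditionMessage(err), "rows 2")
  unlink(c(path, bad_y, holey))
})

test_that("datasets round-trip through CSV within float formatting", {
  set.seed(505)
  d <- make_logistic_data(50, beta = 2, label = "development")
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(d, path, outcome_column = "y")
  back <- read_dataset_csv(path, "y", d$predictor_names, "development")
  expect_identical(back$outcomes, d$outcomes)
  expect_equal(back$covariates, d$covariates, tolerance = 1e-12)
  expect_error(write_dataset_csv(d, path, outcome_column = "x"),
               class = "validisc_error_bad_argument")
  unlink(path)
})

test_that("self-validation report is internally coherent", {
  set.seed(501)
  dev <- make_logistic_data(60, beta = 2, label = "development")
  rep <- validate_external(dev, dev, k = 100, seed = 3)
  expect_equal(rep$ratio, 1)
  expect_identical(rep$c_refitted, rep$c_val)
  expect_gte(rep$perm_p, 0)
  expect_lte(rep$perm_p, 1)
  expect_identical(rep$reject, rep$perm_p < rep$alpha)
})

test_that("single large-sample validations reproduce the benchmark decomposition", {
  set.seed(502)
  dev <- make_logistic_data(1000, beta = 3, sigma = 1, label = "development")

  # heterogeneous case-mix with weaker effects: mbc exceeds the observed c
  val2 <- make_logistic_data(1000, beta = 2, sigma = 1.5, label = "validation")
  r2 <- validate_external(dev, val2, k = 0, seed = 4)
  expect_gt(r2$mbc, r2$c_val)

  # homogeneous populations: mbc tracks the observed c
  val1 <- make_logistic_data(1000, beta = 3, sigma = 1, label = "validation")
  r1 <- validate_external(dev, val1, k = 0, seed = 5)
  expect_lte(abs(r1$mbc - r1$c_val), 0.03)
})

test_that("validation reports round-trip through JSON losslessly", {
  set.seed(503)
  dev <- make_logistic_data(50, beta = 2)
  val <- make_logistic_data(50, beta = 2)
  rep <- validate_external(dev, val, k = 50, seed = 17, study_label = "demo")
  path <- tempfile(fileext = ".json")
  write_validation_report(rep, path)
  back <- read_validation_report(path)
  expect_identical(back$coefficients, rep$coefficients)
  for (f in c("study_label", "c_dev", "c_val", "sd_lp_dev", "sd_lp_val",
              "ratio", "mbc", "c_refitted", "perm_p", "reject", "k",
              "n_reps", "alpha", "seed", "intercept", "converged")) {
    expect_identical(back[[f]], rep[[f]], info = f)
  }
  unlink(path)
})

test_that("reports are reproducible from their recorded seed", {
  set.seed(504)
  dev <- make_logistic_data(50, beta = 2)
  val <- make_logistic_data(50, beta = 2)
  a <- validate_external(dev, val, k = 50, seed = 29)
  b <- validate_external(dev, val, k = 50, seed = 29)
  expect_identical(unclass(a), unclass(b))
})

test_that("the command-line interface runs both subcommands end to end", {
  cli <- system.file("cli", "validisc", package = "validisc")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")

  out_prefix <- tempfile()
  res <- system2(rscript, c(
    cli, "simulate", "--scenario", "all", "--replicates", "2",
    "--no-permutation", "--seed", "7", "--out", out_prefix
  ), stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status") %||% 0L, 0L)
  summary_csv <- read.csv(paste0(out_prefix, ".csv"))
  expect_equal(length(unique(paste(summary_csv$label, summary_csv$n_dev))), 9)

  dev_csv <- toy_csv(local({
    set.seed(61); x <- rnorm(60)
    data.frame(y = rbinom(60, 1, plogis(2 * x)), x = x)
  }))
  val_csv <- toy_csv(local({
    set.seed(62); x <- rnorm(60)
    data.frame(y = rbinom(60, 1, plogis(2 * x)), x = x)
  }))
  rep_json <- tempfile(fileext = ".json")
  res2 <- system2(rscript, c(
    cli, "validate", "--dev", dev_csv, "--val", val_csv,
    "--outcome", "y", "--predictors", "x", "--permutations", "50",
    "--seed", "11", "--out", rep_json
  ), stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res2, "status") %||% 0L, 0L)
  rep <- read_validation_report(rep_json)
  expect_s3_class(rep, "validisc_report")
  expect_true(is.finite(rep$c_val))

  # determinism: same seed, byte-identical report
  rep_json2 <- tempfile(fileext = ".json")
  system2(rscript, c(
    cli, "validate", "--dev", dev_csv, "--val", val_csv,
    "--outcome", "y", "--predictors", "x", "--permutations", "50",
    "--seed", "11", "--out", rep_json2
  ), stdout = TRUE, stderr = TRUE)
  expect_identical(readLines(rep_json), readLines(rep_json2))
  unlink(c(dev_csv, val_csv, rep_json, rep_json2,
           paste0(out_prefix, c(".csv", ".json"))))
})
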