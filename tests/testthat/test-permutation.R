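test_that("the p-value is the strict one-sided proportion and drives rejection", {
  set.seed(401)
  dev <- make_logistic_data(40, beta = 2, label = "development")
  val <- make_logistic_data(40, beta = 2, label = "validation")
  pt <- permutation_test(dev, val, k = 50, seed = 5)
  expect_length(pt$permuted_c, 50)
  expect_equal(pt$p_value, sum(pt$permuted_c < pt$c_observed) / 50,
               tolerance = 1e-12)
  expect_identical(pt$reject, pt$p_value < pt$alpha)
})

test_that("tied permuted c-statistics do not count as smaller", {
  # dev and val are identical tiny samples, so permuted splits frequently
  # reproduce the observed c exactly; those ties must not lower p
  d <- dataset(c(0, 1, 0, 1), cbind(x = c(-1.2, 0.8, -0.3, 1.5)))
  # with 4 + 4 subjects many splits are degenerate, so redraws are expected
  expect_warning(pt <- permutation_test(d, d, k = 60, seed = 9),
                 class = "validisc_warning_many_redraws")
  expect_gt(sum(pt$permuted_c == pt$c_observed), 0)
  expect_equal(pt$p_value, mean(pt$permuted_c < pt$c_observed))
})

test_that("identical seeds reproduce the permuted c vector exactly", {
  set.seed(402)
  dev <- make_logistic_data(30, beta = 2)
  val <- make_logistic_data(30, beta = 2)
  a <- permutation_test(dev, val, k = 100, seed = 123)
  b <- permutation_test(dev, val, k = 100, seed = 123)
  expect_identical(a$permuted_c, b$permuted_c)
  expect_identical(a$p_value, b$p_value)
  d <- permutation_test(dev, val, k = 100, seed = 124)
  expect_false(identical(a$permuted_c, d$permuted_c))
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on 8 subjects", {
  set.seed(403)
  # fixed 4 + 4 instance with mixed outcomes in both halves
  x_all <- c(-1.4, 0.9, -0.2, 1.1, -0.8, 1.7, 0.3, -0.5)
  y_all <- c(0, 1, 0, 1, 0, 1, 1, 0)
  dev <- dataset(y_all[1:4], cbind(x = x_all[1:4]))
  val <- dataset(y_all[5:8], cbind(x = x_all[5:8]))

  # oracle, independent of the package's fitter: glm refit + pairwise c
  # over every fittable assignment of 4 of the 8 subjects to development
  glm_c <- function(idx) {
    yd <- y_all[idx]
    if (sum(yd) %in% c(0, 4)) return(NA_real_)
    fit <- suppressWarnings(
      glm.fit(cbind(1, x_all[idx]), yd, family = binomial())
    )
    lp <- cbind(1, x_all[-idx]) %*% fit$coefficients
    c_stat_pairwise(drop(lp), y_all[-idx])
  }
  c_obs <- glm_c(1:4)
  perm_c <- apply(utils::combn(8, 4), 2, glm_c)
  perm_c <- perm_c[!is.na(perm_c)]
  p_exact <- mean(perm_c < c_obs)

  expect_warning(pt <- permutation_test(dev, val, k = 2000, seed = 11),
                 class = "validisc_warning_many_redraws")
  expect_equal(pt$c_observed, c_obs, tolerance = 1e-10)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(pt$p_value - p_exact), 4 * se + 0.005)
})

test_that("validating a copy of the development set gives central p-values", {
  set.seed(404)
  dev <- make_logistic_data(40, beta = 2)
  ps <- sapply(1:30, function(s) {
    permutation_test(dev, dev, k = 60, seed = 1000 + s)$p_value
  })
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
})

test_that("rejection rate summarizes a collection of tests", {
  set.seed(405)
  dev <- make_logistic_data(30, beta = 2)
  val <- make_logistic_data(30, beta = 2)
  pts <- lapply(1:4, function(s) permutation_test(dev, val, k = 20, seed = s))
  expect_equal(rejection_rate(pts), mean(sapply(pts, `[[`, "reject")))
  all_zero <- lapply(pts, function(p) { p$reject <- TRUE; p })
  expect_equal(rejection_rate(all_zero), 1)
  expect_error(rejection_rate(list()), class = "validisc_error_bad_argument")
  mixed <- pts
  mixed[[1]]$alpha <- 0.10
  expect_error(rejection_rate(mixed), class = "validisc_error_bad_argument")
})

test_that("degenerate inputs are typed errors", {
  dev <- make_logistic_data(20, beta = 1)
  val <- make_logistic_data(20, beta = 1)
  expect_error(permutation_test(dev, val, k = 0),
               class = "validisc_error_bad_argument")
  expect_error(permutation_test(dev, val, alpha = 1.5),
               class = "validisc_error_bad_argument")
  all1 <- dataset(rep(1, 20), cbind(x = rnorm(20)))
  expect_error(permutation_test(all1, all1, k = 10),
               class = "validisc_error_degenerate_outcome")
})
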