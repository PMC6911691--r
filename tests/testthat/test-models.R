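test_that("one-component PLSR on a single band is ordinary least squares", {
  set.seed(41)
  x <- matrix(stats::runif(30, 1, 5))
  y <- 2.5 * x[, 1] + stats::rnorm(30, 0, 0.4)
  fit <- fit_plsr(x, y, 1)
  ols <- stats::lm(y ~ x[, 1])
  expect_equal(fit$fitted, unname(stats::fitted(ols)), tolerance = 1e-10)
  expect_equal(unname(coef(fit)), unname(stats::coef(ols)),
               tolerance = 1e-10)
})

test_that("full-component PLSR matches multiple linear regression", {
  set.seed(42)
  n <- 25; p <- 6
  x <- matrix(stats::rnorm(n * p), n)
  y <- x %*% stats::runif(p, -2, 2) + stats::rnorm(n, 0, 0.2)
  fit <- fit_plsr(x, y, p)
  mlr <- stats::lm(y ~ x)
  expect_equal(fit$fitted, unname(stats::fitted(mlr)), tolerance = 1e-6)
  xnew <- matrix(stats::rnorm(5 * p), 5)
  expect_equal(predict(fit, xnew),
               unname(cbind(1, xnew) %*% stats::coef(mlr))[, 1],
               tolerance = 1e-6)
})

test_that("PLSR survives perfectly collinear bands with equal coefficients", {
  set.seed(43)
  b <- stats::rnorm(20)
  x <- cbind(b, b, stats::rnorm(20))
  y <- 3 * b + stats::rnorm(20, 0, 0.1)
  fit <- fit_plsr(x, y, 2)
  expect_equal(fit$coef[1], fit$coef[2], tolerance = 1e-10)
  expect_true(all(is.finite(fit$fitted)))
})

test_that("PLSR component scores are orthogonal and Rd sums below one", {
  set.seed(44)
  x <- matrix(stats::rnorm(40 * 15), 40)
  y <- x %*% stats::rnorm(15) + stats::rnorm(40)
  fit <- fit_plsr(x, y, 6)
  G <- crossprod(fit$scores)
  off <- max(abs(G[upper.tri(G)])) / max(diag(G))
  expect_lt(off, 1e-8)
  expect_lte(sum(fit$rd), 1 + 1e-12)
  expect_true(all(fit$rd >= 0))
})

test_that("a noiseless three-analyte mixture is recovered almost exactly", {
  cfg <- sim_config(n_samples = 40, wavelengths = seq(400, 1100, 2),
                    analytes = default_analytes()[1:3], noise_sd = 0,
                    scatter_range = c(1, 1), seed = 45)
  sim <- generate_spectra(cfg)
  y <- chem_values(sim$chem, "COD")
  fit <- fit_plsr(sim$spectra$reflectance, y, 3)
  expect_gt(regression_metrics(y, fit$fitted)$r2, 0.999)
})

test_that("the mean calibration spectrum predicts the mean response", {
  set.seed(46)
  x <- matrix(stats::rnorm(30 * 8), 30)
  y <- stats::rnorm(30, 50, 5)
  fit <- fit_plsr(x, y, 3)
  expect_equal(predict(fit, colMeans(x)), mean(y), tolerance = 1e-10)
})

test_that("PLSR rejects invalid sizes and degenerate responses", {
  x <- matrix(stats::rnorm(20), 10)
  expect_error(fit_plsr(x, stats::rnorm(10), 11), "ncomp")
  expect_error(fit_plsr(x, rep(1, 10), 1), "zero variance")
  expect_error(predict(fit_plsr(x, stats::rnorm(10), 2),
                       matrix(1, 1, 5)), "expects")
})

test_that("ELM refits are bit-identical under the same seed", {
  set.seed(47)
  x <- matrix(stats::rnorm(40 * 6), 40)
  y <- stats::rnorm(40)
  f1 <- fit_elm(x, y, 25, seed = 99)
  f2 <- fit_elm(x, y, 25, seed = 99)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(f1$beta, f2$beta)
  f3 <- fit_elm(x, y, 25, seed = 100)
  expect_false(identical(f1$fitted, f3$fitted))
})

test_that("ELM interpolates when the hidden layer is at least n", {
  set.seed(48)
  x <- matrix(stats::rnorm(15 * 3), 15)
  y <- stats::rnorm(15)
  fit <- fit_elm(x, y, 20, seed = 5)
  expect_lt(sqrt(mean((y - fit$fitted)^2)), 1e-6)
})

test_that("ELM training error is non-increasing over nested hidden sizes", {
  set.seed(49)
  x <- matrix(stats::rnorm(60 * 5), 60)
  y <- sin(x[, 1]) + 0.5 * x[, 2] + stats::rnorm(60, 0, 0.1)
  rmse <- vapply(c(1, 2, 5, 10, 20, 40), function(L)
    sqrt(mean(residuals(fit_elm(x, y, L, seed = 7))^2)), numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("ELM learns a linear law to high validation accuracy", {
  set.seed(50)
  x <- matrix(stats::runif(100, -2, 2))
  y <- 2 * x[, 1] + 1
  fit <- fit_elm(x[1:70, , drop = FALSE], y[1:70], 50, seed = 3)
  pred <- predict(fit, x[71:100, , drop = FALSE])
  expect_gt(regression_metrics(y[71:100], pred)$r2, 0.99)
})

test_that("model fitting leaves the caller's RNG stream untouched", {
  set.seed(51)
  x <- matrix(stats::rnorm(20), 10)
  y <- stats::rnorm(10)
  cfg <- small_sim_config(seed = 2, n_samples = 4)
  before <- .Random.seed
  invisible(fit_elm(x, y, 4, seed = 1))
  expect_identical(.Random.seed, before)
  invisible(generate_spectra(cfg))
  expect_identical(.Random.seed, before)
})

test_that("single-row prediction works for both model types", {
  set.seed(52)
  x <- matrix(stats::rnorm(60), 20)
  y <- stats::rnorm(20)
  p1 <- predict(fit_plsr(x, y, 2), x[1, ])
  p2 <- predict(fit_elm(x, y, 8, seed = 2), x[1, ])
  expect_length(p1, 1)
  expect_length(p2, 1)
  expect_true(is.finite(p1) && is.finite(p2))
})

test_that("cross-validated component selection lands near the truth", {
  set.seed(53)
  n <- 60
  lat <- matrix(stats::rnorm(n * 3), n)
  x <- cbind(lat %*% matrix(stats::rnorm(3 * 20), 3),
             matrix(stats::rnorm(n * 10), n) * 0.05)
  y <- lat %*% c(2, -1, 0.5) + stats::rnorm(n, 0, 0.1)
  m <- select_ncomp(x, y)
  expect_gte(m, 2)
  expect_lte(m, 6)
})
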