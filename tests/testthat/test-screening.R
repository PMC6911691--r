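test_that("Pearson screening recovers exact and null correlations", {
  set.seed(21)
  y <- stats::rnorm(20, 10, 2)
  ortho <- stats::residuals(stats::lm(stats::rnorm(20) ~ y))
  x <- cbind(y, ortho, stats::rnorm(20))
  res <- pearson_screen(x, y, wavelengths = c(500, 510, 520),
                        parameter = "COD")
  expect_equal(res$scores[1], 1, tolerance = 1e-12)
  expect_equal(res$scores[2], 0, tolerance = 1e-12)
  expect_true(res$mask[1])
})

test_that("the critical r is derived from the t distribution", {
  set.seed(22)
  x <- matrix(stats::rnorm(87 * 2), 87)
  y <- stats::rnorm(87)
  res <- pearson_screen(x, y, alpha = 0.001)
  # oracle: invert the two-tailed t test at df = n - 2 and map t to r
  tc <- stats::qt(1 - 0.001 / 2, df = 85)
  expect_equal(res$details$critical_r, tc / sqrt(85 + tc^2),
               tolerance = 1e-12)
  expect_equal(res$details$critical_r, 0.3468, tolerance = 1e-3)
  # the critical r must agree with cor.test's p-value at the boundary
  r_edge <- res$details$critical_r
  t_edge <- r_edge * sqrt(85 / (1 - r_edge^2))
  expect_equal(2 * stats::pt(-t_edge, 85), 0.001, tolerance = 1e-10)
})

test_that("constant bands get r = 0 with a warning", {
  x <- cbind(rep(1, 10), 1:10)
  expect_warning(res <- pearson_screen(x, 1:10 + stats::rnorm(10, 0, .1)),
                 "constant band")
  expect_equal(res$scores[1], 0)
  expect_equal(res$details$constant_bands, 1L)
})

test_that("the averaging operator rescales to unit mean", {
  expect_equal(averaging_operator(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(averaging_operator(rep(3.7, 5)), rep(1, 5))
  set.seed(23)
  for (i in 1:10) {
    v <- stats::runif(sample(3:30, 1), 0.1, 5)
    expect_equal(mean(averaging_operator(v)), 1, tolerance = 1e-12)
  }
  expect_error(averaging_operator(c(-1, 1)), "mean is zero")
})

test_that("gray correlation degree matches the hand-computed example", {
  res <- gcd_screen(c(1, 2, 3), matrix(c(3, 2, 1)),
                    gc_config(extrema_scope = "per-band"))
  # normalised (0.5,1,1.5) vs (1.5,1,0.5); differences (1,0,1);
  # coefficients (1/3, 1, 1/3); mean = 5/9
  expect_equal(res$scores, 5 / 9, tolerance = 1e-15)
})

test_that("a proportional factor attains the maximal gray correlation", {
  x0 <- c(1, 2, 3, 5)
  for (scope in c("global", "per-band")) {
    res <- gcd_screen(x0, cbind(3 * x0, c(5, 1, 4, 2)),
                      gc_config(extrema_scope = scope))
    expect_equal(res$scores[1], 1)
  }
})

test_that("gray correlation scores stay in (0, 1]", {
  set.seed(24)
  for (i in 1:20) {
    m <- sample(5:25, 1)
    p <- sample(2:15, 1)
    rho <- stats::runif(1, 0.05, 1)
    sig <- stats::runif(m, 0.5, 10)
    fac <- matrix(stats::runif(m * p, 0.1, 10), m)
    scope <- sample(c("global", "per-band"), 1)
    g <- gcd_screen(sig, fac, gc_config(rho = rho, extrema_scope = scope))
    expect_true(all(g$scores > 0 & g$scores <= 1 + 1e-12))
  }
})

test_that("VIP equals 1 under equal explanatory power and sqrt(2),0 under
           total concentration of weight", {
  p <- 6
  even <- structure(list(weights = matrix(rep(1 / sqrt(p), p)), rd = 0.8),
                    class = "wq_plsr")
  expect_equal(vip_from_fit(even), rep(1, p), tolerance = 1e-12)
  skewed <- structure(list(weights = matrix(c(1, 0)), rd = 0.5),
                      class = "wq_plsr")
  expect_equal(vip_from_fit(skewed), c(sqrt(2), 0), tolerance = 1e-12)
})

test_that("mean squared VIP is 1 for fitted models of any size", {
  set.seed(25)
  for (i in 1:5) {
    n <- sample(15:40, 1); p <- sample(4:60, 1)
    x <- matrix(stats::rnorm(n * p), n)
    y <- x %*% stats::rnorm(p) + stats::rnorm(n, 0, 0.3)
    fit <- fit_plsr(x, y, sample(1:4, 1))
    expect_equal(sum(vip_from_fit(fit)^2), p, tolerance = 1e-8)
  }
})

test_that("vip_screen selects bands above 1 and records the component count", {
  sim <- generate_spectra(small_sim_config(seed = 26))
  snv <- preprocess_spectra(sim$spectra)
  res <- vip_screen(snv, chem_values(sim$chem, "COD"),
                    vip_config(n_components = 4), parameter = "COD")
  expect_equal(res$details$n_components, 4)
  expect_identical(res$mask, res$scores > 1)
  expect_gt(res$n_selected, 0)
  expect_lt(res$n_selected, length(res$scores))
})

test_that("set-pair connection reproduces the counted-degree examples", {
  full <- set_pair_connection(rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(full$s, 7)
  expect_equal(full$mu, 1)

  # n = 10, s = 4, f = 3, p = 3: I = 1/7, mu = 0.4 + 0.3/7 - 0.3
  a <- c(rep(TRUE, 4), rep(TRUE, 3), rep(FALSE, 3))
  b <- c(rep(TRUE, 4), rep(FALSE, 3), rep(FALSE, 3))
  st <- set_pair_connection(a, b, "symmetric")
  expect_equal(c(st$s, st$f, st$p), c(4, 3, 3))
  expect_equal(st$I, 1 / 7)
  expect_equal(st$mu, 0.4 + 0.3 / 7 - 0.3)
  expect_equal(st$mu, 0.14286, tolerance = 1e-4)

  expect_error(set_pair_connection(c(TRUE), c(TRUE, FALSE)), "equal length")
})

test_that("symmetric state with S = P and F*I = 0 has zero connection", {
  st <- set_pair_connection(c(TRUE, FALSE), c(TRUE, FALSE), "symmetric")
  # s = 1, p = 1, f = 0 -> S = P, F = 0 -> mu = 0 requires S = P only
  expect_equal(st$S, st$P)
  expect_equal(st$mu, st$F * st$I)
})

test_that("set-pair degrees always sum to one with mu in [-1, 1]", {
  set.seed(27)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    a <- stats::runif(n) > stats::runif(1)
    b <- stats::runif(n) > stats::runif(1)
    for (conv in c("symmetric", "asymmetric")) {
      st <- set_pair_connection(a, b, conv)
      expect_equal(st$S + st$F + st$P, 1, tolerance = 1e-12)
      expect_true(st$mu >= -1 - 1e-12 && st$mu <= 1 + 1e-12)
      expect_true(st$I >= -1 - 1e-12 && st$I <= 1 + 1e-12)
    }
  }
})

test_that("set-pair weights follow the relative-membership formula", {
  expect_equal(spa_weights(c(1, 1)), c(0.5, 0.5))
  expect_equal(spa_weights(c(1, -1)), c(1, 0))
  expect_equal(spa_weights(c(0.5, -0.5)), c(0.75, 0.25))
  expect_error(spa_weights(c(-1, -1)), "degenerate")
  expect_error(spa_weights(0.5), "two methods")
  set.seed(28)
  for (i in 1:50) {
    w <- spa_weights(stats::runif(sample(2:5, 1), -0.99, 1))
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("degenerate set-pair weights collapse the fusion onto one method", {
  wl <- 1:8
  mk <- function(method, scores, mask, thr)
    specwq:::new_screen_result(method, "COD", wl, scores, mask, thr)
  gc_none <- mk("gc", rep(0.2, 8), rep(FALSE, 8), 0.5)
  vip_all <- mk("vip", rep(1.5, 8), rep(TRUE, 8), 1)
  fused <- spa_screen(gc_none, vip_all)
  expect_equal(unname(fused$details$weights), c(0, 1))
  expect_equal(fused$scores, vip_all$scores)
  expect_identical(fused$mask, vip_all$scores > 1)

  gc_all <- mk("gc", rep(0.8, 8), rep(TRUE, 8), 0.5)
  vip_none <- mk("vip", rep(0.5, 8), rep(FALSE, 8), 1)
  fused2 <- spa_screen(gc_all, vip_none)
  expect_equal(unname(fused2$details$weights), c(1, 0))
  expect_equal(fused2$scores, gc_all$scores)
})

test_that("with equal weights the fused score is the plain average", {
  wl <- 1:4
  mk <- function(method, scores, mask, thr)
    specwq:::new_screen_result(method, "COD", wl, scores, mask, thr)
  # identical masks give mu = (x, x) hence weights (0.5, 0.5)
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  gc <- mk("gc", c(0.6, 0.55, 0.4, 0.3), mask, 0.5)
  vip <- mk("vip", c(1.4, 1.2, 0.8, 0.2), mask, 1)
  fused <- spa_screen(gc, vip)
  expect_equal(unname(fused$details$weights), c(0.5, 0.5))
  expect_equal(fused$scores[1], 0.5 * 0.6 + 0.5 * 1.4)  # = 1.0
  expect_equal(fused$threshold, 0.75)
  expect_true(fused$mask[1])
})

test_that("raising a band's VIP never lowers its fused score", {
  wl <- 1:6
  mk <- function(method, scores, mask, thr)
    specwq:::new_screen_result(method, "COD", wl, scores, mask, thr)
  gc <- mk("gc", c(0.7, 0.6, 0.5, 0.45, 0.4, 0.2),
           c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 0.5)
  vip_lo <- mk("vip", c(1.2, 1.1, 0.9, 0.6, 0.5, 0.4),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 1)
  scores_hi <- vip_lo$scores; scores_hi[3] <- 1.8
  vip_hi <- mk("vip", scores_hi, vip_lo$mask, 1)  # same mask, higher score
  f_lo <- spa_screen(gc, vip_lo)
  f_hi <- spa_screen(gc, vip_hi)
  expect_gte(f_hi$scores[3], f_lo$scores[3])
})

test_that("select_bands subsets columns and refuses empty masks", {
  set.seed(29)
  x <- matrix(stats::rnorm(50), 10)
  res <- specwq:::new_screen_result("gc", "COD", seq(500, 540, 10),
                                    stats::runif(5),
                                    c(TRUE, FALSE, TRUE, FALSE, TRUE), 0.5)
  sel <- select_bands(res, x)
  expect_equal(sel$wavelengths, c(500, 520, 540))
  expect_equal(sel$x, x[, c(1, 3, 5)])
  res$mask <- rep(FALSE, 5)
  expect_error(select_bands(res, x), "relax the threshold")
  all_true <- specwq:::new_screen_result("gc", "COD", seq(500, 540, 10),
                                         stats::runif(5), rep(TRUE, 5), 0)
  expect_equal(select_bands(all_true, x)$x, x)
})
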