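test_that("a perfect forecast scores rmse 0, mape 0, r2 1", {
  a <- c(3, 7, 5, 9, 4)
  m <- compute_metrics(a, a)
  expect_equal(m$rmse, 0)
  expect_equal(m$mape, 0)
  expect_equal(m$r2, 1)
})

test_that("hand-computed two-day example matches", {
  m <- compute_metrics(c(2, 2), c(1, 4))
  expect_equal(m$rmse, sqrt((1 + 4) / 2))
  expect_equal(m$mape, 75)  # (100% + 50%) / 2
})

test_that("metrics agree with loop-based oracles to 1e-10", {
  withr::with_seed(31, {
    p <- runif(1000, 5, 40)
    a <- pmax(1, round(p + rnorm(1000, 0, 4)))
  })
  m <- compute_metrics(p, a)
  n <- length(a)
  rmse_loop <- 0; for (i in 1:n) rmse_loop <- rmse_loop + (p[i] - a[i])^2
  rmse_loop <- sqrt(rmse_loop / n)
  mape_loop <- 0; for (i in 1:n) mape_loop <- mape_loop + abs(p[i] - a[i]) / a[i]
  mape_loop <- mape_loop / n * 100
  mp <- mean(p); ma <- mean(a); sxy <- 0; sxx <- 0; syy <- 0
  for (i in 1:n) {
    sxy <- sxy + (p[i] - mp) * (a[i] - ma)
    sxx <- sxx + (p[i] - mp)^2
    syy <- syy + (a[i] - ma)^2
  }
  r2_loop <- (sxy / sqrt(sxx * syy))^2
  expect_equal(m$rmse, rmse_loop, tolerance = 1e-10)
  expect_equal(m$mape, mape_loop, tolerance = 1e-10)
  expect_equal(m$r2, r2_loop, tolerance = 1e-10)
  # metrics are order-invariant
  perm <- withr::with_seed(5, sample.int(n))
  m2 <- compute_metrics(p[perm], a[perm])
  expect_equal(m[c("rmse", "r2", "mape")], m2[c("rmse", "r2", "mape")])
})

test_that("zero-demand days are excluded from MAPE and reported", {
  expect_message(m <- compute_metrics(c(1, 2, 3), c(0, 2, 3)), "excluded 1")
  expect_identical(m$n_zero_excluded, 1L)
  expect_equal(m$mape, 0)
  expect_error(compute_metrics(c(1, 2), c(0, 0)), "undefined")
})

test_that("the bootstrap collapses on constants and is seed-deterministic", {
  const <- bootstrap_ci(rep(4, 20), mean, n_boot = 200, seed = 1)
  expect_equal(const$lower, 4)
  expect_equal(const$upper, 4)
  x <- withr::with_seed(9, rnorm(50))
  expect_identical(bootstrap_ci(x, mean, n_boot = 500, seed = 7),
                   bootstrap_ci(x, mean, n_boot = 500, seed = 7))
  expect_error(bootstrap_ci(1:5), "at least 10")
})

test_that("bootstrap interval width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(100, 400), function(n) {
    x <- withr::with_seed(13, rnorm(n))
    ci <- bootstrap_ci(x, mean, n_boot = 1500, seed = 3)
    ci$upper - ci$lower
  }, numeric(1))
  expect_gt(widths[1] / widths[2], 1.5)
  expect_lt(widths[1] / widths[2], 2.7)
})

test_that("the CI-to-p conversion reproduces the closed-form normal computation", {
  p <- ci_difference_pvalue(10, c(8, 12), 13, c(11, 15))
  se <- (12 - 8) / (2 * 1.96)
  p_oracle <- 2 * pnorm(-abs(10 - 13) / sqrt(2 * se^2))
  expect_equal(p, p_oracle, tolerance = 1e-12)
  expect_equal(p, 0.0376271, tolerance = 1e-5)
})

test_that("the p-value behaves at the null and under widening intervals", {
  expect_equal(ci_difference_pvalue(5, c(4, 6), 5, c(4.5, 5.5)), 1)
  expect_equal(ci_difference_pvalue(5, c(5, 5), 5, c(5, 5)), 1)
  expect_warning(p0 <- ci_difference_pvalue(5, c(5, 5), 6, c(6, 6)), "zero")
  expect_equal(p0, 0)
  p_base <- ci_difference_pvalue(10, c(9, 11), 12, c(11, 13))
  for (wid in c(1.5, 2.5, 4)) {
    p_wide <- ci_difference_pvalue(10, c(10 - wid, 10 + wid), 12, c(11, 13))
    expect_gte(p_wide, p_base)
  }
})

test_that("evaluate_forecasts reports both horizons with ordered intervals", {
  dm <- build_design_matrix(make_raw(160, seed = 6), min_nonzero = 60)
  fc <- rolling_origin_forecast(dm, pl7_forecaster(), initial_train = 100,
                                step = 20)
  ev <- suppressMessages(evaluate_forecasts(fc, dm, n_boot = 200, seed = 2))
  expect_identical(nrow(ev), 6L)
  expect_setequal(unique(ev$horizon), c(2, 4))
  expect_true(all(ev$lower <= ev$estimate + 1e-12))
  expect_true(all(ev$estimate <= ev$upper + 1e-12))
})
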