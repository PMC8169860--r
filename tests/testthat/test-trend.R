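test_that("PACF of white noise stays inside the significance band", {
  set.seed(40)
  x <- rnorm(500)
  pv <- compute_pacf(x, max_lag = 10)
  expect_true(mean(abs(pv) < 1.96 / sqrt(500)) >= 0.9)
  expect_true(all(abs(pv) <= 1))
})

test_that("PACF recovers the lag-1 coefficient of an AR(1) process", {
  set.seed(41)
  x <- as.numeric(arima.sim(list(ar = 0.8), 500))
  pv <- compute_pacf(x, max_lag = 5)
  expect_equal(pv[1], 0.8, tolerance = 0.1)
  # cross-check against the Durbin-Levinson PACF from stats
  ref <- drop(stats::pacf(x, lag.max = 5, plot = FALSE)$acf)
  expect_equal(pv, ref, tolerance = 0.05)
})

test_that("a deterministic linear series has lag-1 PACF near one", {
  pv <- compute_pacf(as.numeric(1:50), max_lag = 3)
  expect_equal(pv[1], 1, tolerance = 0.01)
})

test_that("constant series yield a degenerate zero PACF", {
  pv <- compute_pacf(rep(2.5, 30), max_lag = 4)
  expect_equal(as.numeric(pv), rep(0, 4))
  expect_true(attr(pv, "degenerate"))
})

test_that("order selection takes the largest significant PACF lag", {
  expect_equal(select_order(c(0.9, 0.05, 0.02), 100), 1L)
  expect_equal(select_order(c(0.9, 0.4, 0.02), 100), 2L)
  expect_equal(select_order(c(0.05, 0.03, 0.01), 100), 1L)   # fallback
  # invariant to the sign of the PACF values
  set.seed(42)
  for (i in 1:10) {
    pv <- runif(5, -0.5, 0.5)
    expect_equal(select_order(pv, 80), select_order(-pv, 80))
  }
})

test_that("conditional least squares recovers exact AR recursions", {
  x <- 0.5^(0:19)                       # x_y = 0.5 x_{y-1}, x_1 = 1
  m <- fit_ar(x, 1)
  expect_equal(m$betas, 0.5, tolerance = 1e-8)
  expect_equal(m$beta0, 0, tolerance = 1e-8)
  expect_equal(forecast_ar(m, x), 0.5 * x[20], tolerance = 1e-8)

  # an exact AR(2) recursion is reproduced one step ahead
  x2 <- numeric(30); x2[1:2] <- c(1, 0.8)
  for (t in 3:30) x2[t] <- 0.2 + 0.6 * x2[t - 1] + 0.25 * x2[t - 2]
  m2 <- fit_ar(x2[1:29], 2)
  expect_equal(forecast_ar(m2, x2[1:29]), x2[30], tolerance = 1e-8)
})

test_that("AR(1) estimation is consistent on simulated data", {
  set.seed(43)
  x <- 1 + as.numeric(arima.sim(list(ar = 0.8), 200, sd = 0.1))
  m <- fit_ar(x, 1)
  expect_gte(m$betas, 0.7)
  expect_lte(m$betas, 0.9)
  expect_lt(abs(mean(m$residuals)), 1e-8)
  # cross-check against stats::ar.ols as an independent fitter
  ref <- stats::ar.ols(x, order.max = 1, aic = FALSE, demean = TRUE)
  expect_equal(unname(m$betas), drop(ref$ar), tolerance = 1e-6)
})

test_that("constant series degrade to a fixed-point intercept model", {
  x <- rep(3.7, 20)
  m <- fit_ar(x, 2)
  expect_true(m$degenerate)
  expect_equal(forecast_ar(m, x), 3.7, tolerance = 1e-12)
})

test_that("one-step forecasts substitute lags and clip to bounds", {
  m <- structure(list(order = 1L, beta0 = 0, betas = 0.5, residual_sd = 0),
                 class = "ar_model")
  expect_equal(forecast_ar(m, c(1, 0.25)), 0.125)
  fc <- forecast_ar(m, c(1, 0.25), bounds = c(0.2, 1))
  expect_equal(as.numeric(fc), 0.2)
  expect_true(attr(fc, "clipped"))
  # multi-step recursion
  fc3 <- forecast_ar(m, c(1, 0.8), horizon = 3)
  expect_equal(fc3, 0.8 * 0.5^(1:3))
})

test_that("unit-root diagnostics behave as expected under both hypotheses", {
  set.seed(44)
  rw <- cumsum(rnorm(300))
  a_rw <- adf_test(rw)
  expect_gt(a_rw$pvalue, 0.05)

  set.seed(45)
  st <- as.numeric(arima.sim(list(ar = 0.2), 300))
  a_st <- adf_test(st)
  expect_lt(a_st$pvalue, 0.05)

  expect_true(adf_test(c(rep(1, 15)))$degenerate)
})

test_that("the trend fit is advisory-diagnostic: ADF never gates the AR fit", {
  x <- 1:40 + 0.01 * rnorm(40)          # trending, unit-root-ish series
  tr <- fit_trend(x)
  expect_s3_class(tr$model, "ar_model")
  expect_true(is.finite(tr$diagnostics$adf_pvalue))
  expect_gte(tr$diagnostics$selected_order, 1L)
  # the linear fallback fits the same series
  lin <- fit_trend(x, method = "linear")
  expect_equal(lin$model$slope, 1, tolerance = 0.01)
  expect_equal(forecast_linear_trend(lin$model), 41, tolerance = 0.5)
})
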