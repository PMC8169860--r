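test_that("input scaling round-trips through the unit hypercube", {
  specs <- default_parameter_specs()
  b <- param_bounds(specs)
  set.seed(11)
  for (i in 1:20) {
    u <- runif(ncol(b))
    theta <- drop(unit_to_scale(u, b))
    expect_equal(drop(scale_to_unit(theta, b)), setNames(u, colnames(b)),
                 tolerance = 1e-12)
    expect_true(in_bounds(theta, b))
  }
})

test_that("GP posterior interpolates training data and reverts to the prior", {
  set.seed(4)
  X <- matrix(runif(12), ncol = 2)
  f <- 3 + 10 * rowSums(X^2)
  gp <- fit_gp(list(X = X, f = f), kernel_spec("matern52"))
  p <- predict(gp, X, standardized = TRUE)
  y_std <- (f - gp$y_mean) / gp$y_sd
  expect_lt(max(abs(p$mean - y_std)), 1e-3)
  # sd at training inputs is bounded by the jitter scale
  expect_lt(max(p$sd), sqrt(gp$jitter) * 10)

  # two-point case: prediction at a training input recovers the observation
  gp2 <- fit_gp(list(X = matrix(c(0.2, 0.8), ncol = 1), f = c(1, 2)),
                kernel_spec("squared-exponential", tune_by_likelihood = FALSE))
  p2 <- predict(gp2, matrix(c(0.2, 0.8), ncol = 1), standardized = TRUE)
  expect_lt(max(abs(p2$mean - gp2$y)), 1e-6)

  # far from all data the posterior reverts to prior mean and variance
  far <- predict(gp2, matrix(25, ncol = 1))
  expect_equal(far$mean, gp2$y_mean, tolerance = 1e-6)
  expect_equal(far$sd, gp2$y_sd * sqrt(gp2$kernel$signal_variance),
               tolerance = 1e-6)
})

test_that("GP predictions match an independent dense-solve oracle", {
  set.seed(5)
  X <- matrix(sort(runif(5)), ncol = 1)
  f <- drop(X)                         # f(x) = x
  kern <- kernel_spec("matern52", length_scale = 0.4, signal_variance = 1.2,
                      tune_by_likelihood = FALSE)
  gp <- fit_gp(list(X = X, f = f), kern, jitter = 1e-6)
  Xstar <- matrix(seq(0, 1, length.out = 21), ncol = 1)
  p <- predict(gp, Xstar, standardized = TRUE)
  o <- gp_oracle_matern52(X, gp$y, Xstar, ls = 0.4, sv = 1.2, jitter = 1e-6)
  expect_equal(p$mean, o$mean, tolerance = 1e-8)
  expect_equal(p$sd, o$sd, tolerance = 1e-6)

  # mean at the midpoint of two close training points lies between their values
  mid <- (X[2, 1] + X[3, 1]) / 2
  pm <- predict(gp, matrix(mid, ncol = 1))$mean
  expect_gte(pm, min(f[2:3]) - 1e-9)
  expect_lte(pm, max(f[2:3]) + 1e-9)
})

test_that("duplicate inputs are merged with a warning", {
  X <- matrix(c(0.1, 0.1, 0.9), ncol = 1)
  f <- c(1, 3, 5)
  expect_warning(gp <- fit_gp(list(X = X, f = f), kernel_spec()), "duplicate")
  expect_equal(nrow(gp$X), 2L)
  # merged objective is the average of the duplicates
  expect_equal(gp$y_mean, mean(c(2, 5)))
})

test_that("acquisition closed forms match their degenerate and z = 0 limits", {
  ei <- acquisition_spec("expected-improvement", xi = 0)
  pi_ <- acquisition_spec("probability-of-improvement", xi = 0)
  lcb <- acquisition_spec("lower-confidence-bound", kappa = 2)

  # deterministic limit: sigma = 0
  expect_equal(acquisition_score(ei, mu = 0.5, sigma = 0, f_best = 1), 0.5)
  expect_equal(acquisition_score(ei, mu = 1.5, sigma = 0, f_best = 1), 0)
  expect_equal(acquisition_score(pi_, mu = 0.5, sigma = 0, f_best = 1), 1)
  expect_equal(acquisition_score(pi_, mu = 1.5, sigma = 0, f_best = 1), 0)

  # z = 0 closed forms
  expect_equal(acquisition_score(ei, mu = 1, sigma = 1, f_best = 1),
               dnorm(0), tolerance = 1e-12)
  expect_equal(acquisition_score(pi_, mu = 1, sigma = 1, f_best = 1), 0.5)

  expect_equal(acquisition_score(lcb, mu = 2, sigma = 0.5, f_best = NA), -1)
})

test_that("EI is non-negative everywhere and increases with sigma", {
  ei <- acquisition_spec("expected-improvement", xi = 0.01)
  set.seed(6)
  mu <- rnorm(200); sigma <- runif(200, 0, 3)
  expect_true(all(acquisition_score(ei, mu, sigma, f_best = 0.2) >= 0))

  sig_grid <- seq(0.01, 3, length.out = 50)
  vals <- acquisition_score(ei, mu = rep(-0.5, 50), sigma = sig_grid,
                            f_best = 0)
  expect_true(all(diff(vals) > 0))
})

test_that("proposals explore away from zero-variance training points", {
  X <- rbind(c(0.5, 0.5), c(0.52, 0.48))
  gp <- fit_gp(list(X = X, f = c(1, 1.1)),
               kernel_spec(tune_by_likelihood = FALSE))
  set.seed(8)
  u <- propose_next(gp, acquisition_spec("expected-improvement"), restarts = 5)
  expect_true(all(u >= 0 & u <= 1))
  expect_gt(min(sqrt(rowSums(sweep(X, 2, u)^2))), 1e-3)
})

test_that("more restarts never yield a worse proposal", {
  set.seed(9)
  X <- matrix(runif(30), ncol = 2)
  f <- sin(8 * X[, 1]) * cos(8 * X[, 2])
  gp <- fit_gp(list(X = X, f = f), kernel_spec("matern52"))
  acq <- acquisition_spec("expected-improvement")
  set.seed(101); u1 <- propose_next(gp, acq, restarts = 1)
  set.seed(101); u20 <- propose_next(gp, acq, restarts = 20)
  expect_gte(acquisition_value(acq, gp, u20), acquisition_value(acq, gp, u1))
})

test_that("LCB with kappa = 0 finds the posterior-mean minimizer (grid oracle)", {
  set.seed(10)
  X <- matrix(c(0.05, 0.3, 0.5, 0.7, 0.95), ncol = 1)
  f <- (drop(X) - 0.45)^2
  gp <- fit_gp(list(X = X, f = f),
               kernel_spec("squared-exponential", length_scale = 0.3,
                           tune_by_likelihood = FALSE))
  grid <- matrix(seq(0, 1, length.out = 10001), ncol = 1)
  mean_grid <- predict(gp, grid)$mean
  x_star <- grid[which.min(mean_grid), 1]
  set.seed(12)
  u <- propose_next(gp, acquisition_spec("lower-confidence-bound", kappa = 0),
                    restarts = 10)
  expect_equal(u, x_star, tolerance = 1e-3)
})
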