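# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# Brute-force length-weighted average: scan all windows for containment of
# year y, weight each covering window by its length.
brute_force_yearly_average <- function(estimates, y, ws) {
  w <- ws$windows
  cover <- which(w$start_year <= y & y <= w$end_year)
  keys <- paste(w$kind, w$index, sep = ":")
  ekeys <- vapply(estimates, function(e)
    paste(e$window$kind, e$window$index, sep = ":"), "")
  num <- 0; den <- 0
  for (i in cover) {
    e <- estimates[[match(keys[i], ekeys)]]
    num <- num + w$length[i] * e$values
    den <- den + w$length[i]
  }
  num / den
}

# Random window estimates over a window set, one d-vector per window.
random_estimates <- function(ws, d = 3, seed = 1) {
  set.seed(seed)
  lapply(seq_len(nrow(ws$windows)), function(i)
    window_estimate(ws$windows[i, ], stats::rnorm(d), objective = 0))
}

# Exact GP regression by direct dense solve (no Cholesky reuse, no package
# internals): mean and sd at query points for a Matern-5/2 kernel.
gp_oracle_matern52 <- function(X, y, Xstar, ls, sv, jitter) {
  kfun <- function(A, B) {
    K <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      r <- sqrt(sum((A[i, ] - B[j, ])^2))
      s <- sqrt(5) * r / ls
      K[i, j] <- sv * (1 + s + s^2 / 3) * exp(-s)
    }
    K
  }
  K <- kfun(X, X) + diag(jitter, nrow(X))
  Ks <- kfun(Xstar, X)
  Kinv <- solve(K)
  list(mean = drop(Ks %*% Kinv %*% y),
       sd = sqrt(pmax(sv - diag(Ks %*% Kinv %*% t(Ks)), 0)))
}

# Assemble a calibration_result by hand from exact window estimates,
# bypassing the optimizer (used to test the forecasting chain in isolation).
manual_calibration_result <- function(theta_by_window, windowing, specs,
                                      locations, location_county) {
  ws <- build_windows(windowing)
  res <- list(estimates = list(), series = list(), trends = list(),
              windowing = windowing, pbo_config = NULL, specs = specs,
              model_id = "manual", locations = locations,
              location_county = location_county, traces = NULL)
  for (loc in locations) {
    est <- lapply(seq_len(nrow(ws$windows)), function(i)
      window_estimate(ws$windows[i, ], theta_by_window[[i]], objective = 0))
    res$estimates[[loc]] <- est
    sr <- yearly_parameter_series(est, windowing)
    res$series[[loc]] <- sr
    res$trends[[loc]] <- lapply(
      stats::setNames(colnames(sr$values), colnames(sr$values)),
      function(p) fit_trend(sr$values[, p]))
  }
  structure(res, class = "calibration_result")
}

quadratic_bounds <- rbind(lower = c(0, 0), upper = c(1, 1))
quadratic_objective <- function(x) sum((x - 0.3)^2)
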