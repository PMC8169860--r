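#' Partial autocorrelation function (sequential-regression definition)
#'
#' The PACF at lag `k` is the lag-`k` coefficient of an order-`k`
#' autoregression fitted by ordinary least squares with an intercept. This is
#' the quantity used to pick the autoregressive order of a parameter's yearly
#' trend.
#'
#' @param series Numeric yearly series.
#' @param max_lag Largest lag; needs `length(series) > max_lag + 1`.
#' @return Numeric vector of PACF values at lags `1 .. max_lag`, clamped to
#'   `[-1, 1]`; for a (near-)constant series, zeros with attribute
#'   `degenerate = TRUE`.
#' @export
compute_pacf <- function(series, max_lag = 10) {
  series <- as.numeric(series)
  n <- length(series)
  max_lag <- as.integer(max_lag)
  if (n <= max_lag + 1L) {
    stop("compute_pacf: series length must exceed max_lag + 1", call. = FALSE)
  }
  if (stats::sd(series) < 1e-12) {
    return(structure(rep(0, max_lag), degenerate = TRUE))
  }
  out <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    yk <- series[(k + 1L):n]
    Xk <- cbind(1, vapply(seq_len(k), function(j) series[(k + 1L - j):(n - j)],
                          numeric(n - k)))
    fit <- stats::lm.fit(Xk, yk)
    out[k] <- fit$coefficients[k + 1L]
  }
  out[!is.finite(out)] <- 0
  pmin(pmax(out, -1), 1)
}

#' Select autoregressive order from the PACF
#'
#' Picks the largest lag whose PACF magnitude exceeds the 95% white-noise
#' band `1.96 / sqrt(length)`; if no lag is significant, falls back to order 1.
#'
#' @param pacf_values PACF at lags `1 .. max_order` (or longer).
#' @param n_obs Length of the series the PACF came from.
#' @param max_order Largest admissible order.
#' @return Integer order `t >= 1`.
#' @export
select_order <- function(pacf_values, n_obs, max_order = length(pacf_values)) {
  stopifnot(max_order >= 1)
  k <- seq_len(min(max_order, length(pacf_values)))
  band <- 1.96 / sqrt(n_obs)
  sig <- which(abs(pacf_values[k]) > band)
  if (length(sig)) max(sig) else 1L
}

#' Fit an autoregressive trend model
#'
#' Fits `x_y = beta0 + sum_i beta_i x_{y-i} + eps_y` by conditional least
#' squares (OLS on the lagged design over observations `t+1 .. Y`). A
#' singular design (e.g. a constant series) degrades to an intercept-only
#' model, flagged via `degenerate`.
#'
#' @param series Numeric yearly series of length `>= 2t + 2`.
#' @param t Autoregressive order (`>= 1`).
#' @return An object of class `ar_model` with `order`, `beta0`, `betas`,
#'   `residual_sd`, `fitted`, `residuals`, `degenerate`.
#' @export
fit_ar <- function(series, t) {
  series <- as.numeric(series)
  t <- as.integer(t)
  n <- length(series)
  stopifnot(t >= 1L)
  if (n < 2L * t + 2L) {
    stop("fit_ar: series length ", n, " too short for order ", t,
         " (need >= ", 2L * t + 2L, ")", call. = FALSE)
  }
  y <- series[(t + 1L):n]
  X <- cbind(1, vapply(seq_len(t), function(j) series[(t + 1L - j):(n - j)],
                       numeric(n - t)))
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  degenerate <- anyNA(co)
  if (degenerate) {
    co <- c(mean(y), rep(0, t))
    res <- y - co[1]
  } else {
    res <- fit$residuals
  }
  dfree <- max(length(y) - (if (degenerate) 1L else t + 1L), 1L)
  structure(list(order = t, beta0 = unname(co[1]), betas = unname(co[-1]),
                 residual_sd = sqrt(sum(res^2) / dfree),
                 fitted = y - res, residuals = res,
                 n_obs = n, degenerate = degenerate),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> AR(%d): beta0 = %.4g, betas = (%s), residual sd %.4g%s\n",
              x$order, x$beta0, paste(signif(x$betas, 4), collapse = ", "),
              x$residual_sd, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Forecast from a fitted autoregressive model
#'
#' One-step forecast `beta0 + sum_i beta_i * series[Y+1-i]`; further steps by
#' recursive substitution. If a [parameter_spec()] (or `c(lower, upper)`) is
#' given, forecasts are clipped into the bounds and flagged.
#'
#' @param model An [fit_ar()] result.
#' @param series The observed series the forecast continues.
#' @param horizon Number of steps ahead.
#' @param bounds Optional `parameter_spec` or length-2 numeric `c(lower,
#'   upper)`.
#' @return Numeric forecast vector of length `horizon`, with attribute
#'   `clipped` (logical vector) when `bounds` is supplied.
#' @export
forecast_ar <- function(model, series, horizon = 1, bounds = NULL) {
  stopifnot(inherits(model, "ar_model"))
  series <- as.numeric(series)
  if (length(series) < model$order) {
    stop("forecast_ar: series shorter than model order", call. = FALSE)
  }
  ext <- series
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    lags <- ext[length(ext) - seq_len(model$order) + 1L]
    out[h] <- model$beta0 + sum(model$betas * lags)
    ext <- c(ext, out[h])
  }
  if (!is.null(bounds)) {
    if (inherits(bounds, "parameter_spec")) bounds <- c(bounds$lower, bounds$upper)
    clipped <- out < bounds[1] | out > bounds[2]
    out <- pmin(pmax(out, bounds[1]), bounds[2])
    attr(out, "clipped") <- clipped
  }
  out
}

#' Linear-in-year trend model (alternative to the autoregression)
#'
#' Fits `x_y = a + b * y` by least squares; the forecast extrapolates the
#' line. Provided as the simple fallback trend fitter for near-linear
#' parameter trajectories.
#'
#' @param series Numeric yearly series.
#' @return An object of class `linear_trend` with `intercept`, `slope`,
#'   `residual_sd`.
#' @export
fit_linear_trend <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  stopifnot(n >= 3L)
  yr <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, yr), series)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 residual_sd = sqrt(sum(fit$residuals^2) / max(n - 2L, 1L)),
                 n_obs = n),
            class = "linear_trend")
}

#' @rdname fit_linear_trend
#' @param model A `linear_trend` fit.
#' @param horizon Steps beyond the fitted series.
#' @param bounds Optional bounds as in [forecast_ar()].
#' @export
forecast_linear_trend <- function(model, horizon = 1, bounds = NULL) {
  stopifnot(inherits(model, "linear_trend"))
  out <- model$intercept + model$slope * (model$n_obs + seq_len(horizon))
  if (!is.null(bounds)) {
    if (inherits(bounds, "parameter_spec")) bounds <- c(bounds$lower, bounds$upper)
    clipped <- out < bounds[1] | out > bounds[2]
    out <- pmin(pmax(out, bounds[1]), bounds[2])
    attr(out, "clipped") <- clipped
  }
  out
}

# MacKinnon (1994) approximate asymptotic p-value for the Dickey-Fuller tau
# statistic, constant-only regression, one I(1) series. Outside the tabulated
# range the p-value saturates at 0 or 1.
mackinnon_pvalue_c <- function(stat) {
  if (stat > 2.74) return(1)
  if (stat < -18.83) return(0)
  co <- if (stat <= -1.61) c(2.1659, 1.4412, 0.038269)
        else c(1.7339, 0.93202, -0.12745, -0.010368)
  stats::pnorm(sum(co * stat^(seq_along(co) - 1L)))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests for a unit root with a constant-only Dickey-Fuller regression
#' `diff(x)_t = a + rho * x_{t-1} + sum_i g_i diff(x)_{t-i} + e_t`; the number
#' of augmentation lags is chosen by AIC from `0 .. max_lags`. The p-value
#' uses the MacKinnon (1994) response-surface approximation. In this package
#' the test is a diagnostic of autocorrelation in parameter trends only — it
#' never gates the autoregressive fit.
#'
#' @param series Numeric series of length `>= 10`.
#' @param max_lags Largest augmentation lag; default `floor((length - 1) / 3)`.
#' @return A list with `statistic`, `pvalue`, `lags_used`, `degenerate`.
#' @export
adf_test <- function(series, max_lags = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) stop("adf_test: need a series of length >= 10", call. = FALSE)
  if (stats::sd(series) < 1e-12) {
    return(list(statistic = NA_real_, pvalue = NA_real_, lags_used = NA_integer_,
                degenerate = TRUE))
  }
  if (is.null(max_lags)) max_lags <- (n - 1L) %/% 3L
  max_lags <- min(as.integer(max_lags), n - 5L)
  dx <- diff(series)

  fit_one <- function(p) {
    # common sample across candidate lags would be stricter; use per-p sample
    idx <- (p + 1L):length(dx)
    yv <- dx[idx]
    Xm <- cbind(1, series[idx])
    if (p > 0L) {
      Xm <- cbind(Xm, vapply(seq_len(p), function(j) dx[idx - j],
                             numeric(length(idx))))
    }
    fit <- stats::lm.fit(Xm, yv)
    rss <- sum(fit$residuals^2)
    nob <- length(yv)
    k <- ncol(Xm)
    list(aic = nob * log(rss / nob) + 2 * k, fit = fit, X = Xm, rss = rss,
         nobs = nob, k = k)
  }

  cands <- lapply(0:max_lags, fit_one)
  best_p <- which.min(vapply(cands, `[[`, numeric(1), "aic")) - 1L
  b <- cands[[best_p + 1L]]
  sigma2 <- b$rss / (b$nobs - b$k)
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(b$X))), error = function(e) NULL)
  if (is.null(XtX_inv)) {
    return(list(statistic = NA_real_, pvalue = NA_real_,
                lags_used = best_p, degenerate = TRUE))
  }
  se_rho <- sqrt(sigma2 * XtX_inv[2, 2])
  stat <- b$fit$coefficients[2] / se_rho
  list(statistic = unname(stat), pvalue = mackinnon_pvalue_c(stat),
       lags_used = best_p, degenerate = FALSE)
}

#' Fit trend model for a yearly parameter series
#'
#' Convenience wrapper chaining [compute_pacf()], [select_order()],
#' [fit_ar()] and [adf_test()] for one parameter's yearly series, as done per
#' (location, parameter) by [calibrate()].
#'
#' @param series Numeric yearly series.
#' @param max_order Cap on the autoregressive order; default
#'   `min(5, floor(length(series) / 6))`.
#' @param method `"ar"` (default) or `"linear"` for the linear-in-year
#'   fallback.
#' @return A list with the fitted `model`, `diagnostics` (PACF, selected
#'   order, ADF outputs) and `method`.
#' @export
fit_trend <- function(series, max_order = NULL, method = c("ar", "linear")) {
  method <- match.arg(method)
  series <- as.numeric(series)
  n <- length(series)
  if (method == "linear") {
    return(list(model = fit_linear_trend(series), diagnostics = NULL,
                method = "linear"))
  }
  if (is.null(max_order)) max_order <- max(1L, min(5L, n %/% 6L))
  max_lag <- min(max_order, n - 2L)
  pv <- compute_pacf(series, max_lag = max_lag)
  t_sel <- select_order(pv, n, max_order = max_lag)
  t_sel <- min(t_sel, max(1L, (n - 2L) %/% 2L))   # keep the fit well-posed
  model <- fit_ar(series, t_sel)
  adf <- adf_test(series)
  list(model = model,
       diagnostics = list(pacf = as.numeric(pv), selected_order = t_sel,
                          adf_statistic = adf$statistic,
                          adf_pvalue = adf$pvalue,
                          adf_lags = adf$lags_used,
                          degenerate = isTRUE(attr(pv, "degenerate")) ||
                            isTRUE(adf$degenerate)),
       method = "ar")
}
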