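#' A pluggable crop-model interface
#'
#' The calibration pipeline treats the crop model as a black box with the
#' contract `simulate(theta, env, year) -> yield (kg/ha)`, deterministic for
#' fixed inputs within one calibration run. [toycrop_model()] is the built-in
#' implementation; an external simulator (e.g. an APSIM runner) can be
#' plugged in by wrapping its invocation in this interface.
#'
#' @param simulate Function `(theta, env, year) -> numeric yield`.
#' @param id Identifier string.
#' @return An object of class `crop_model_interface`.
#' @export
crop_model_interface <- function(simulate, id = "custom") {
  stopifnot(is.function(simulate))
  structure(list(simulate = simulate, id = id),
            class = "crop_model_interface")
}

#' Per-window calibration objective
#'
#' Builds the loss minimized for one time-window at one location: the RMSE
#' (kg/ha) between the model's yields and the observed county yields over the
#' window's years, with the parameter vector held constant across those
#' years.
#'
#' @param model A [crop_model_interface()].
#' @param env The location's environment.
#' @param observed Numeric vector of observed county yields indexed by
#'   training year.
#' @param window One row of a window set's `windows` data frame.
#' @return A function `theta -> RMSE`.
#' @export
window_objective <- function(model, env, observed, window) {
  yrs <- seq.int(window$start_year, window$end_year)
  if (any(yrs > length(observed)) || anyNA(observed[yrs])) {
    stop("window_objective: observed yields missing for window years ",
         window$start_year, "..", window$end_year, call. = FALSE)
  }
  obs <- observed[yrs]
  function(theta) {
    pred <- vapply(yrs, function(y) model$simulate(theta, env, y), numeric(1))
    sqrt(mean((pred - obs)^2))
  }
}

#' Calibrate time-dependent parameters
#'
#' Runs the full framework on a dataset: for each location, every window of
#' the scheme (main and auxiliary, all with the same optimizer budget) is
#' calibrated by [run_pbo()] against the county observed series; per-year
#' parameter vectors are formed by [yearly_weighted_average()]; and each
#' parameter's yearly series gets an autoregressive trend fit with PACF order
#' selection and the ADF diagnostic. All random number streams derive from
#' `pbo_cfg$seed`, so a rerun reproduces the result exactly.
#'
#' @param dataset A `toycrop_dataset` (or a list with the same `observed`,
#'   `environments`, `specs` fields).
#' @param model A [crop_model_interface()].
#' @param windowing A [windowing_config()]; its `Y` must match the dataset
#'   years.
#' @param pbo_cfg A [pbo_config()] used (with per-window derived seeds) for
#'   every window.
#' @param locations Optional character vector of location ids to calibrate;
#'   default all. Calibration is independent per location.
#' @param trend_max_order Cap on the autoregressive order per parameter.
#' @param keep_traces If `TRUE`, retain a compact per-window optimizer trace
#'   (iteration, instance, objective, incumbent) for serialization.
#' @return An object of class `calibration_result`: per-location window
#'   estimates, yearly parameter series, trend fits, plus the configs.
#' @export
calibrate <- function(dataset, model, windowing, pbo_cfg,
                      locations = NULL, trend_max_order = NULL,
                      keep_traces = FALSE) {
  stopifnot(inherits(model, "crop_model_interface"),
            inherits(windowing, "windowing_config"),
            inherits(pbo_cfg, "pbo_config"))
  if (windowing$Y != max(dataset$observed$year_index)) {
    stop("calibrate: windowing Y (", windowing$Y,
         ") does not match dataset years (",
         max(dataset$observed$year_index), ")", call. = FALSE)
  }
  ws <- build_windows(windowing)
  bounds <- param_bounds(dataset$specs)
  if (is.null(locations)) locations <- names(dataset$environments)
  stopifnot(all(locations %in% names(dataset$environments)))

  obs_by_county <- split(dataset$observed, dataset$observed$county)
  county_series <- lapply(obs_by_county, function(d)
    d$yield_kg_ha[order(d$year_index)])

  estimates <- list(); series <- list(); trends <- list(); traces <- list()
  for (li in seq_along(locations)) {
    loc <- locations[li]
    env <- dataset$environments[[loc]]
    observed <- county_series[[env$county]]
    est <- vector("list", nrow(ws$windows))
    trc <- if (keep_traces) vector("list", nrow(ws$windows)) else NULL
    for (wi in seq_len(nrow(ws$windows))) {
      win <- ws$windows[wi, ]
      obj <- window_objective(model, env, observed, win)
      cfg <- pbo_cfg
      cfg$seed <- derive_seed(pbo_cfg$seed, li, wi)
      tr <- tryCatch(run_pbo(obj, bounds, cfg), error = function(e) e)
      if (inherits(tr, "error")) {
        cfg$seed <- derive_seed(pbo_cfg$seed, li, wi + 100000L)
        tr <- tryCatch(run_pbo(obj, bounds, cfg), error = function(e) e)
        if (inherits(tr, "error")) {
          stop("calibrate: optimization failed twice for location ", loc,
               ", window ", win$kind, ":", win$index, " (",
               conditionMessage(tr), ")", call. = FALSE)
        }
      }
      est[[wi]] <- window_estimate(win, tr$best_theta, tr$best_objective)
      if (keep_traces) {
        trc[[wi]] <- data.frame(location = loc, kind = win$kind,
                                window_index = win$index,
                                iteration = tr$iteration,
                                instance = tr$instance,
                                objective = tr$f, incumbent = cummin(tr$f))
      }
    }
    estimates[[loc]] <- est
    if (keep_traces) traces[[loc]] <- trc
    sr <- yearly_parameter_series(est, windowing)
    series[[loc]] <- sr
    trends[[loc]] <- lapply(
      stats::setNames(colnames(sr$values), colnames(sr$values)),
      function(p) fit_trend(sr$values[, p], max_order = trend_max_order))
  }

  structure(list(estimates = estimates, series = series, trends = trends,
                 windowing = windowing, pbo_config = pbo_cfg,
                 specs = dataset$specs, model_id = model$id,
                 locations = locations,
                 location_county = vapply(dataset$environments[locations],
                                          `[[`, "", "county"),
                 traces = if (keep_traces) traces else NULL),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %d location(s), %d windows each, Y = %d, n = %d, model '%s'\n",
    length(x$locations), length(x$estimates[[1]]), x$windowing$Y,
    x$windowing$n, x$model_id))
  invisible(x)
}

#' Forecast parameters and predict the test year
#'
#' Forecasts each parameter one year beyond the training period from its
#' fitted trend model (clipped into the parameter bounds), simulates each
#' calibrated location at the test year, and aggregates locations to county
#' level by the median (robust to outlier locations).
#'
#' @param result A [calibrate()] result.
#' @param model A [crop_model_interface()].
#' @param envs The environment list the result was calibrated against.
#' @param test_year Training-year index to predict; default `Y + 1`.
#' @return A list with `theta` (per-location forecast parameter vectors),
#'   `location_predictions` (data frame `location`, `county`, `yield_kg_ha`)
#'   and `county_predictions` (data frame `county`, `yield_kg_ha`).
#' @export
predict_test_year <- function(result, model, envs,
                              test_year = result$windowing$Y + 1L) {
  stopifnot(inherits(result, "calibration_result"),
            inherits(model, "crop_model_interface"))
  b <- param_bounds(result$specs)
  horizon <- test_year - result$windowing$Y
  stopifnot(horizon >= 1)

  theta_hat <- list()
  loc_pred <- data.frame(location = result$locations,
                         county = unname(result$location_county),
                         yield_kg_ha = NA_real_)
  for (li in seq_along(result$locations)) {
    loc <- result$locations[li]
    sv <- result$series[[loc]]$values
    th <- vapply(colnames(sv), function(p) {
      tr <- result$trends[[loc]][[p]]
      bd <- c(b["lower", p], b["upper", p])
      fc <- if (tr$method == "ar") {
        forecast_ar(tr$model, sv[, p], horizon = horizon, bounds = bd)
      } else {
        forecast_linear_trend(tr$model, horizon = horizon, bounds = bd)
      }
      fc[horizon]
    }, numeric(1))
    theta_hat[[loc]] <- th
    loc_pred$yield_kg_ha[li] <- model$simulate(th, envs[[loc]], test_year)
  }
  county_pred <- stats::aggregate(yield_kg_ha ~ county, data = loc_pred,
                                  FUN = stats::median)
  list(theta = theta_hat, location_predictions = loc_pred,
       county_predictions = county_pred)
}

#' Yield evaluation metrics
#'
#' `rmse` is the root mean squared difference in kg/ha; `rrmse` expresses it
#' as a percentage of the mean observed value; `r2` is the coefficient of
#' determination `1 - SS_res / SS_tot` (negative when predictions are worse
#' than the observed mean).
#'
#' @param pred,obs Equal-length numeric vectors of predicted and observed
#'   yields.
#' @return A single numeric value.
#' @export
rmse <- function(pred, obs) {
  check_paired(pred, obs)
  sqrt(mean((pred - obs)^2))
}

#' @rdname rmse
#' @export
rrmse <- function(pred, obs) {
  check_paired(pred, obs)
  m <- mean(obs)
  if (abs(m) < 1e-12) stop("rrmse: mean of observed is zero", call. = FALSE)
  100 * rmse(pred, obs) / m
}

#' @rdname rmse
#' @export
r2 <- function(pred, obs) {
  check_paired(pred, obs)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot < 1e-12) {
    warning("r2: observed values have zero variance; R^2 undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - sum((obs - pred)^2) / ss_tot
}

check_paired <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) == 0L) {
    stop("predicted and observed vectors must be non-empty and of equal length",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize calibration outputs
#'
#' `write_yearly_parameters_csv` writes one row per (location, calendar year)
#' with a column per parameter; `write_ar_models_json` writes the trend fits
#' and diagnostics per (location, parameter), including the one-step forecast.
#'
#' @param result A `calibration_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_yearly_parameters_csv <- function(result, path) {
  rows <- lapply(result$locations, function(loc) {
    v <- result$series[[loc]]$values
    cbind(data.frame(location = loc, year = as.integer(rownames(v))),
          as.data.frame(v))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_yearly_parameters_csv
#' @export
write_ar_models_json <- function(result, path) {
  b <- param_bounds(result$specs)
  out <- lapply(result$locations, function(loc) {
    sv <- result$series[[loc]]$values
    lapply(stats::setNames(colnames(sv), colnames(sv)), function(p) {
      tr <- result$trends[[loc]][[p]]
      bd <- c(b["lower", p], b["upper", p])
      fc <- if (tr$method == "ar") {
        forecast_ar(tr$model, sv[, p], bounds = bd)
      } else {
        forecast_linear_trend(tr$model, bounds = bd)
      }
      c(list(method = tr$method),
        if (tr$method == "ar") list(
          order = tr$model$order, beta0 = tr$model$beta0,
          betas = as.numeric(tr$model$betas),
          residual_sd = tr$model$residual_sd,
          pacf = tr$diagnostics$pacf,
          adf_statistic = tr$diagnostics$adf_statistic,
          adf_pvalue = tr$diagnostics$adf_pvalue)
        else list(intercept = tr$model$intercept, slope = tr$model$slope,
                  residual_sd = tr$model$residual_sd),
        list(forecast = as.numeric(fc),
             clipped = isTRUE(any(attr(fc, "clipped")))))
    })
  })
  names(out) <- result$locations
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
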