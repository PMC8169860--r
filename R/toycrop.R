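#' Yield-index weights of the synthetic crop response
#'
#' The synthetic simulator maps a cultivar parameter vector to a
#' dimensionless yield index `G(theta) = 1 + sum_j w_j (u_j - 0.5)`, where
#' `u_j` is parameter `j` scaled into `[0, 1]` by its bounds. The fixed
#' weights make radiation use efficiency and the grain components the main
#' positive drivers, give small negative weight to the thermal-time and
#' leaf-appearance parameters, and zero weight to grain N concentration and
#' transpiration efficiency (which carry no consistent historical trend).
#' `G` ranges over `[0.5, 1.5]` since the absolute weights sum to 1.
#'
#' @return Named numeric weight vector over the nine default parameters.
#' @export
toycrop_weights <- function() {
  c(tt_emerg_to_endjuv = -0.05,
    tt_flower_to_maturity = 0.15,
    head_grain_no_max = 0.20,
    grain_gth_rate = 0.20,
    tt_flower_to_start_grain = -0.05,
    n_conc_crit_grain = 0,
    leaf_app_rate1 = -0.05,
    rue = 0.30,
    transp_eff_cf = 0)
}

#' Yield index of a parameter vector
#'
#' @param theta Named parameter vector in original units (all nine default
#'   parameters).
#' @param specs Parameter specs defining the bounds.
#' @return `G(theta)`, the dimensionless yield index in `[0.5, 1.5]`.
#' @export
yield_index <- function(theta, specs = default_parameter_specs()) {
  w <- toycrop_weights()
  theta <- align_theta(theta, names(w))
  u <- drop(scale_to_unit(theta, param_bounds(specs)[, names(w)]))
  unname(1 + sum(w * (u - 0.5)))
}

# order a parameter vector by name, accepting unnamed vectors in spec order
align_theta <- function(theta, parameter_names) {
  if (is.null(names(theta))) {
    stopifnot(length(theta) == length(parameter_names))
    stats::setNames(theta, parameter_names)
  } else {
    miss <- setdiff(parameter_names, names(theta))
    if (length(miss)) {
      stop("missing parameter(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    theta[parameter_names]
  }
}

#' Noiseless yield of the synthetic crop model
#'
#' `yield = base_potential * soil_factor * G(theta) * (1 + anomaly(county,
#' y))`, in kg/ha. The environment carries the county yield potential, the
#' location's multiplicative soil productivity and the county-by-year growing
#' season anomaly (zero for years outside the generated range, e.g. a test
#' year).
#'
#' @param theta Named parameter vector; must lie within the spec bounds.
#' @param env One environment from [generate_dataset()] (a list with
#'   `base_potential`, `soil_factor`, `anomaly`).
#' @param y Training-year index.
#' @param specs Parameter specs defining the bounds.
#' @return Yield in kg/ha.
#' @export
yield_response <- function(theta, env, y, specs = default_parameter_specs()) {
  b <- param_bounds(specs)
  theta <- align_theta(theta, colnames(b))
  if (!in_bounds(theta, b, tol = 1e-9)) {
    stop("yield_response: theta outside parameter bounds", call. = FALSE)
  }
  anom <- if (y >= 1 && y <= length(env$anomaly)) env$anomaly[[y]] else 0
  env$base_potential * env$soil_factor * yield_index(theta, specs) * (1 + anom)
}

#' True time-varying parameter trajectory
#'
#' The ground truth the synthetic data are generated from: parameters with
#' positive yield-index weight move linearly from scaled position 0.3 to 0.7
#' over years `1 .. Y` (breeding progress), negative-weight parameters move
#' from 0.7 to 0.3, and zero-weight parameters stay at 0.5. The resulting
#' yield index rises linearly from 0.8 to 1.2 — a 1.5-fold yield increase
#' over the period, matching the shape of the historical county yield record.
#'
#' @param Y Number of years (`>= 2`).
#' @param specs Parameter specs defining bounds and units.
#' @return An object of class `synthetic_truth`: `theta` (a `Y` x 9 matrix in
#'   original units), `slopes` (per-parameter change per year, original
#'   units), and `specs`.
#' @export
true_trajectory <- function(Y, specs = default_parameter_specs()) {
  stopifnot(Y >= 2)
  w <- toycrop_weights()
  b <- param_bounds(specs)[, names(w)]
  frac <- (seq_len(Y) - 1) / (Y - 1)
  U <- vapply(names(w), function(p) {
    if (w[[p]] > 0) 0.3 + 0.4 * frac
    else if (w[[p]] < 0) 0.7 - 0.4 * frac
    else rep(0.5, Y)
  }, numeric(Y))
  theta <- unit_to_scale(U, b)
  colnames(theta) <- names(w)
  span <- b["upper", ] - b["lower", ]
  slopes <- ifelse(w > 0, 0.4, ifelse(w < 0, -0.4, 0)) * span / (Y - 1)
  structure(list(theta = theta, slopes = slopes, specs = specs, Y = Y),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d years x %d parameters; yield index %.3g -> %.3g\n",
              x$Y, ncol(x$theta),
              yield_index(x$theta[1, ], x$specs),
              yield_index(x$theta[x$Y, ], x$specs)))
  invisible(x)
}

#' Generate a synthetic county-yield dataset with known ground truth
#'
#' Emulates the case-study layout: `C` counties with `K` locations (soils)
#' each, observed for `Y` years at county level. County yield potential is
#' drawn uniformly on 9000-11000 kg/ha, location soil factors uniformly on
#' `soil_range`, county-by-year season anomalies normally with sd
#' `anomaly_sd`, and the county observation is the mean of its locations'
#' noiseless yields plus measurement noise of sd `noise_sd`. All draws come
#' from the seeded generator, so identical seeds give identical datasets.
#'
#' @param counties,soils,years Layout: `C` counties x `K` locations, `Y`
#'   years.
#' @param noise_sd Observation noise sd in kg/ha.
#' @param seed Master seed.
#' @param first_year Calendar year of training-year 1.
#' @param soil_range Range of the uniform soil-factor draw.
#' @param anomaly_sd Sd of the multiplicative season anomaly.
#' @param specs Parameter specs.
#' @return An object of class `toycrop_dataset`: `observed` (data frame
#'   `county`, `year`, `yield_kg_ha`), `environments` (list of per-location
#'   environments), `truth` (a [true_trajectory()] plus `noise_sd` and
#'   `seed`), `specs`, and the layout fields.
#' @examples
#' ds <- generate_dataset(counties = 2, soils = 2, years = 12, seed = 42)
#' head(ds$observed)
#' @export
generate_dataset <- function(counties = 5, soils = 5, years = 34,
                             noise_sd = 250, seed = 1L, first_year = 1985L,
                             soil_range = c(0.85, 1.10), anomaly_sd = 0.08,
                             specs = default_parameter_specs()) {
  stopifnot(counties >= 1, soils >= 1, years >= 2)
  truth <- true_trajectory(years, specs)
  truth$noise_sd <- noise_sd
  truth$seed <- as.integer(seed)

  set.seed(derive_seed(seed, 17, 29))
  county_ids <- paste0("county", seq_len(counties))
  base_potential <- stats::setNames(stats::runif(counties, 9000, 11000),
                                    county_ids)
  anomalies <- matrix(stats::rnorm(counties * years, 0, anomaly_sd),
                      nrow = counties,
                      dimnames = list(county_ids, NULL))

  environments <- list()
  for (ci in seq_len(counties)) {
    for (k in seq_len(soils)) {
      loc_id <- sprintf("%s_loc%d", county_ids[ci], k)
      environments[[loc_id]] <- list(
        county = county_ids[ci], location = loc_id,
        base_potential = base_potential[[ci]],
        soil_factor = stats::runif(1, soil_range[1], soil_range[2]),
        anomaly = anomalies[ci, ])
    }
  }

  obs <- expand.grid(county = county_ids, year_index = seq_len(years),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  obs <- obs[order(obs$county, obs$year_index), ]
  loc_county <- vapply(environments, `[[`, "", "county")
  obs$yield_kg_ha <- NA_real_
  for (r in seq_len(nrow(obs))) {
    y <- obs$year_index[r]
    locs <- environments[loc_county == obs$county[r]]
    yl <- vapply(locs, function(e) yield_response(truth$theta[y, ], e, y, specs),
                 numeric(1))
    obs$yield_kg_ha[r] <- mean(yl) + stats::rnorm(1, 0, noise_sd)
  }
  obs$year <- first_year + obs$year_index - 1L
  rownames(obs) <- NULL

  structure(list(observed = obs[, c("county", "year", "year_index",
                                    "yield_kg_ha")],
                 environments = environments, truth = truth, specs = specs,
                 counties = county_ids, soils = soils, years = years,
                 first_year = as.integer(first_year), seed = as.integer(seed)),
            class = "toycrop_dataset")
}

#' @export
print.toycrop_dataset <- function(x, ...) {
  cat(sprintf(
    "<toycrop_dataset> %d counties x %d locations, %d years (%d..%d), noise sd %g kg/ha\n",
    length(x$counties), x$soils, x$years, x$first_year,
    x$first_year + x$years - 1L, x$truth$noise_sd))
  invisible(x)
}

#' The synthetic crop model as a pluggable interface
#'
#' Wraps [yield_response()] into the callable contract used by
#' [calibrate()]: `simulate(theta, env, year) -> kg/ha`, deterministic for
#' fixed inputs.
#'
#' @param specs Parameter specs.
#' @return An object of class `crop_model_interface`.
#' @export
toycrop_model <- function(specs = default_parameter_specs()) {
  crop_model_interface(
    simulate = function(theta, env, year) yield_response(theta, env, year, specs),
    id = "toycrop")
}

#' Write synthetic-dataset components to disk
#'
#' `write_observed_csv` writes the county yield observations
#' (`county,year,yield_kg_ha`, calendar years); `write_environments_json` the
#' environment definitions; `write_truth_json` the ground-truth trajectory
#' (kept separate from calibration inputs).
#'
#' @param dataset A `toycrop_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observed_csv <- function(dataset, path) {
  utils::write.csv(dataset$observed[, c("county", "year", "yield_kg_ha")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
write_environments_json <- function(dataset, path) {
  envs <- lapply(dataset$environments, function(e)
    list(county = e$county, location = e$location,
         base_potential = e$base_potential, soil_factor = e$soil_factor,
         anomaly = as.numeric(e$anomaly)))
  jsonlite::write_json(list(first_year = dataset$first_year,
                            environments = envs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
write_truth_json <- function(dataset, path) {
  tr <- dataset$truth
  jsonlite::write_json(
    list(years = tr$Y, noise_sd = tr$noise_sd, seed = tr$seed,
         slopes = as.list(tr$slopes),
         theta = as.data.frame(tr$theta)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read observed county yields from CSV
#'
#' Inverse of [write_observed_csv()]: expects columns `county`, `year`,
#' `yield_kg_ha` with calendar years.
#'
#' @param path CSV file path.
#' @param first_year Calendar year of training-year index 1; defaults to the
#'   earliest year present.
#' @return A data frame with `county`, `year`, `year_index`, `yield_kg_ha`.
#' @export
read_observed_csv <- function(path, first_year = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("county", "year", "yield_kg_ha")
  if (!all(need %in% names(d))) {
    stop("read_observed_csv: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(first_year)) first_year <- min(d$year)
  d$year_index <- d$year - first_year + 1L
  d[, c("county", "year", "year_index", "yield_kg_ha")]
}
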