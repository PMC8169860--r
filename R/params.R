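#' Define a bounded cultivar parameter
#'
#' A parameter spec names one crop-model cultivar parameter together with its
#' physiological bounds and units. Optimization is always carried out inside
#' these bounds, and forecasts of parameter trends are clipped back into them.
#'
#' @param name Parameter identifier (e.g. `"rue"`).
#' @param lower,upper Numeric bounds, `lower < upper`, in `units`.
#' @param units Unit string (informational).
#' @return An object of class `parameter_spec`.
#' @seealso [default_parameter_specs()]
#' @export
parameter_spec <- function(name, lower, upper, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("parameter_spec: need finite bounds with lower < upper for '",
         name, "'", call. = FALSE)
  }
  structure(list(name = name, lower = lower, upper = upper, units = units),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat(sprintf("<parameter_spec> %s in [%g, %g] %s\n",
              x$name, x$lower, x$upper, x$units))
  invisible(x)
}

#' Default maize cultivar parameter space
#'
#' The nine cultivar parameters calibrated in the maize case study, with the
#' physiological ranges used to bound the search: thermal-time durations of
#' phenological phases, grain number and growth-rate potentials, leaf
#' appearance rate, radiation use efficiency, grain nitrogen concentration and
#' transpiration efficiency.
#'
#' @return A named list of [parameter_spec()] objects (length 9).
#' @examples
#' specs <- default_parameter_specs()
#' names(specs)
#' @export
default_parameter_specs <- function() {
  sp <- list(
    parameter_spec("tt_emerg_to_endjuv",       150,   300,   "degCd"),
    parameter_spec("tt_flower_to_maturity",    600,   900,   "degCd"),
    parameter_spec("head_grain_no_max",        600,   850,   "kernel/ear"),
    parameter_spec("grain_gth_rate",             5,     9,   "mg/grain/d"),
    parameter_spec("tt_flower_to_start_grain", 120,   200,   "degCd"),
    parameter_spec("n_conc_crit_grain",        0.008, 0.016, "g N/g biomass"),
    parameter_spec("leaf_app_rate1",            50,    75,   "deg day"),
    parameter_spec("rue",                      1.4,   1.85,  "g dm/mj"),
    parameter_spec("transp_eff_cf",            0.075, 0.095, "kpa")
  )
  stats::setNames(sp, vapply(sp, `[[`, "", "name"))
}

#' Bounds matrix of a parameter-spec list
#'
#' @param specs A list of [parameter_spec()] objects.
#' @return A 2-row matrix with rows `lower`, `upper` and one column per
#'   parameter.
#' @export
param_bounds <- function(specs) {
  specs <- as_parameter_specs(specs)
  m <- vapply(specs, function(s) c(s$lower, s$upper), numeric(2))
  rownames(m) <- c("lower", "upper")
  colnames(m) <- unname(vapply(specs, `[[`, "", "name"))
  m
}

as_parameter_specs <- function(specs) {
  if (inherits(specs, "parameter_spec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1), "parameter_spec")
  if (!all(ok)) stop("expected a list of parameter_spec objects", call. = FALSE)
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Scale parameters to and from the unit hypercube
#'
#' Surrogate models operate on inputs scaled to `[0, 1]^d` by the parameter
#' bounds, so that a single length scale is meaningful across parameters of
#' very different physical units.
#'
#' @param theta Numeric vector (or matrix with one row per point) in original
#'   units.
#' @param bounds Bounds matrix from [param_bounds()], or a list of specs.
#' @return The scaled (resp. unscaled) vector or matrix.
#' @export
scale_to_unit <- function(theta, bounds) {
  bounds <- as_bounds(bounds)
  out <- sweep(sweep(as_point_matrix(theta, ncol(bounds)), 2, bounds["lower", ]),
               2, bounds["upper", ] - bounds["lower", ], "/")
  if (is.null(colnames(out))) colnames(out) <- colnames(bounds)
  out
}

#' @rdname scale_to_unit
#' @param u Scaled coordinates in `[0, 1]^d`.
#' @export
unit_to_scale <- function(u, bounds) {
  bounds <- as_bounds(bounds)
  out <- sweep(sweep(as_point_matrix(u, ncol(bounds)), 2,
                     bounds["upper", ] - bounds["lower", ], "*"),
               2, bounds["lower", ], "+")
  if (is.null(colnames(out))) colnames(out) <- colnames(bounds)
  out
}

as_bounds <- function(bounds) {
  if (is.list(bounds)) bounds <- param_bounds(bounds)
  stopifnot(is.matrix(bounds), nrow(bounds) == 2L)
  if (is.null(rownames(bounds))) rownames(bounds) <- c("lower", "upper")
  if (any(bounds["upper", ] <= bounds["lower", ])) {
    stop("bounds must satisfy lower < upper", call. = FALSE)
  }
  bounds
}

as_point_matrix <- function(x, d) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == d)
    x
  } else {
    stopifnot(length(x) == d)
    matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  }
}

#' Check that parameter values lie within bounds
#'
#' @inheritParams scale_to_unit
#' @param tol Slack allowed beyond each bound (absolute units).
#' @return Logical scalar (for a vector) or vector (for a matrix of points).
#' @export
in_bounds <- function(theta, bounds, tol = 0) {
  bounds <- as_bounds(bounds)
  x <- as_point_matrix(theta, ncol(bounds))
  apply(x, 1L, function(row) {
    all(row >= bounds["lower", ] - tol) && all(row <= bounds["upper", ] + tol)
  })
}

clip_to_bounds <- function(theta, bounds) {
  bounds <- as_bounds(bounds)
  pmin(pmax(theta, bounds["lower", ]), bounds["upper", ])
}
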