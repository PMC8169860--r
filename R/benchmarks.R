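#' County RMSE benchmarks from the maize case study
#'
#' Published county-level RMSE values (kg/ha, with RRMSE in percent) over the
#' 1985-2018 simulation period for three calibration approaches — manual
#' calibration, the framework with single-instance Bayesian optimization, and
#' the framework with parallel Bayesian optimization — across five US Corn
#' Belt counties. Shipped as plain CSV in `extdata`; used to recompute the
#' headline percent error reductions.
#'
#' @return A data frame with columns `county`, `state`, `manual_rmse`,
#'   `manual_rrmse_pct`, `bo_rmse`, `bo_rrmse_pct`, `pbo_rmse`,
#'   `pbo_rrmse_pct`.
#' @export
county_rmse_benchmarks <- function() {
  path <- system.file("extdata", "county_rmse_benchmarks.csv",
                      package = "tdcal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Percent reduction between two error values
#'
#' `100 * (from - to) / from`, rounded to the nearest integer by default —
#' the convention used when reporting, e.g., how much the parallel optimizer
#' reduced a county's RMSE relative to another calibration method.
#'
#' @param from Baseline error.
#' @param to Improved error.
#' @param digits Rounding digits (`0` for nearest integer; `NULL` to skip).
#' @return Numeric percent reduction(s).
#' @export
percent_reduction <- function(from, to, digits = 0) {
  out <- 100 * (from - to) / from
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Benchmark RMSE reductions of the parallel optimizer
#'
#' Recomputes, from [county_rmse_benchmarks()], the percent RMSE reduction of
#' the PBO-calibrated model relative to manual calibration and to
#' single-instance BO for every benchmark county.
#'
#' @return A data frame with `county`, `pbo_vs_manual_pct`, `pbo_vs_bo_pct`
#'   (nearest-integer percents).
#' @examples
#' rmse_reduction_table()
#' @export
rmse_reduction_table <- function() {
  b <- county_rmse_benchmarks()
  data.frame(county = b$county,
             pbo_vs_manual_pct = percent_reduction(b$manual_rmse, b$pbo_rmse),
             pbo_vs_bo_pct = percent_reduction(b$bo_rmse, b$pbo_rmse))
}
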