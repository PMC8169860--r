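#' Windowing configuration
#'
#' Settings for the overlapping time-window scheme: `Y` training years are
#' covered by main windows of `n` consecutive years (successive main windows
#' overlap by `n - 1` years) plus shorter auxiliary windows at both edges so
#' that every year is covered by exactly `n` windows.
#'
#' @param Y Number of training years; must satisfy `Y >= 2 * n`.
#' @param n Main-window length in years, `n >= 2`.
#' @param first_year Calendar year of training-year index 1 (presentation
#'   only; all internal indices are 1-based training years).
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(Y, n, first_year = 1L) {
  Y <- as.integer(Y); n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop("windowing_config: main-window length n must be >= 2 (got ", n, ")",
         call. = FALSE)
  }
  if (is.na(Y) || Y < 2L * n) {
    stop("windowing_config: need Y >= 2n training years (got Y = ", Y,
         ", n = ", n, ")", call. = FALSE)
  }
  structure(list(Y = Y, n = n, first_year = as.integer(first_year)),
            class = "windowing_config")
}

#' Build the main and auxiliary time-windows
#'
#' Main window `i` covers training years `i .. i+n-1` for
#' `i = 1 .. Y-n+1`. Head auxiliary windows (index `i = 2 .. n`) cover years
#' `1 .. i-1`; tail auxiliary windows (index `i = Y-2n+2 .. Y-n`) cover years
#' `i+n .. Y`. Under this scheme every training year lies in exactly `n`
#' windows, and a window's weight in the per-year average equals its length.
#'
#' @param config A [windowing_config()].
#' @return An object of class `window_set`: the config plus a data frame
#'   `windows` with columns `index`, `kind` (`"main"`, `"aux_head"`,
#'   `"aux_tail"`), `start_year`, `end_year`, `length`.
#' @examples
#' ws <- build_windows(windowing_config(Y = 34, n = 5))
#' table(ws$windows$kind)
#' @export
build_windows <- function(config) {
  stopifnot(inherits(config, "windowing_config"))
  Y <- config$Y; n <- config$n
  main <- data.frame(index = seq_len(Y - n + 1L), kind = "main",
                     start_year = seq_len(Y - n + 1L),
                     end_year = seq_len(Y - n + 1L) + n - 1L)
  head_idx <- seq.int(2L, n)
  aux_head <- data.frame(index = head_idx, kind = "aux_head",
                         start_year = 1L, end_year = head_idx - 1L)
  tail_idx <- seq.int(Y - 2L * n + 2L, Y - n)
  aux_tail <- data.frame(index = tail_idx, kind = "aux_tail",
                         start_year = tail_idx + n, end_year = Y)
  w <- rbind(main, aux_head, aux_tail)
  w$length <- w$end_year - w$start_year + 1L
  rownames(w) <- NULL
  structure(list(config = config, windows = w), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  k <- table(x$windows$kind)
  cat(sprintf(
    "<window_set> Y = %d, n = %d: %d main, %d head-auxiliary, %d tail-auxiliary windows\n",
    x$config$Y, x$config$n, k[["main"]], k[["aux_head"]], k[["aux_tail"]]))
  invisible(x)
}

#' Windows covering a given training year
#'
#' @param ws A [build_windows()] result.
#' @param y Training-year index in `1 .. Y`.
#' @return The subset of `ws$windows` whose span contains `y`; always exactly
#'   `n` rows.
#' @export
covering_windows <- function(ws, y) {
  stopifnot(inherits(ws, "window_set"))
  y <- as.integer(y)
  if (is.na(y) || y < 1L || y > ws$config$Y) {
    stop("covering_windows: year index ", y, " outside 1..", ws$config$Y,
         call. = FALSE)
  }
  w <- ws$windows
  w[w$start_year <= y & y <= w$end_year, , drop = FALSE]
}

#' Per-year combination weights
#'
#' The weight of each window covering year `y`, by the three-branch rule: for
#' early years (`y < n`) the `y` covering main windows get weight `n` and the
#' head auxiliaries of index `i = y+1 .. n` get weight `i - 1`; for central
#' years the `n` covering main windows share weight equally; for late years
#' (`y > Y - n + 1`) the covering main windows get weight `n` and the tail
#' auxiliaries of index `i = Y-2n+2 .. y-n` get weight `Y - n - i + 1`. In
#' every branch a window's weight is its length and the weights are normalized
#' to sum to one.
#'
#' @param config A [windowing_config()].
#' @param y Training-year index.
#' @return A data frame with columns `kind`, `index`, `weight` (summing to 1).
#' @export
year_weights <- function(config, y) {
  stopifnot(inherits(config, "windowing_config"))
  Y <- config$Y; n <- config$n
  y <- as.integer(y)
  if (is.na(y) || y < 1L || y > Y) {
    stop("year_weights: year index ", y, " outside 1..", Y, call. = FALSE)
  }
  if (y < n) {
    main_i <- seq_len(y)
    aux_i <- seq.int(y + 1L, n)
    d <- data.frame(
      kind = c(rep("main", length(main_i)), rep("aux_head", length(aux_i))),
      index = c(main_i, aux_i),
      weight = c(rep(n, length(main_i)), aux_i - 1L))
  } else if (y <= Y - n + 1L) {
    main_i <- seq.int(y - n + 1L, y)
    d <- data.frame(kind = "main", index = main_i, weight = 1)
  } else {
    main_i <- seq.int(y - n + 1L, Y - n + 1L)
    aux_i <- seq.int(Y - 2L * n + 2L, y - n)
    d <- data.frame(
      kind = c(rep("main", length(main_i)), rep("aux_tail", length(aux_i))),
      index = c(main_i, aux_i),
      weight = c(rep(n, length(main_i)), Y - n - aux_i + 1L))
  }
  d$weight <- d$weight / sum(d$weight)
  d
}

#' A per-window parameter estimate
#'
#' @param window One row of `ws$windows` (data frame or list with `index`,
#'   `kind`).
#' @param values Named numeric vector of calibrated parameter values.
#' @param objective Achieved loss for this window (kg/ha RMSE).
#' @return An object of class `window_estimate`.
#' @export
window_estimate <- function(window, values, objective = NA_real_) {
  stopifnot(is.numeric(values))
  structure(list(window = as.list(window)[c("index", "kind", "start_year",
                                            "end_year", "length")],
                 values = values, objective = as.numeric(objective)),
            class = "window_estimate")
}

estimate_key <- function(kind, index) paste(kind, index, sep = ":")

#' Length-weighted per-year parameter values
#'
#' Combines the per-window parameter estimates covering year `y` into the
#' year's parameter vector using [year_weights()]. For central years
#' (`n <= y <= Y - n + 1`) this is the unweighted mean of the `n` covering
#' main-window estimates.
#'
#' @param estimates A list of [window_estimate()] objects, one per window of
#'   the scheme.
#' @param y Training-year index.
#' @param config A [windowing_config()].
#' @return Named numeric parameter vector.
#' @export
yearly_weighted_average <- function(estimates, y, config) {
  w <- year_weights(config, y)
  keyed <- stats::setNames(
    estimates,
    vapply(estimates, function(e) estimate_key(e$window$kind, e$window$index), ""))
  need <- estimate_key(w$kind, w$index)
  miss <- setdiff(need, names(keyed))
  if (length(miss)) {
    stop("yearly_weighted_average: missing estimate for window(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- vapply(keyed[need], `[[`, numeric(length(keyed[[need[1]]]$values)),
                 "values")
  vals <- matrix(vals, ncol = length(need))
  out <- drop(vals %*% w$weight)
  names(out) <- names(keyed[[need[1]]]$values)
  out
}

#' Per-year parameter series over all training years
#'
#' @inheritParams yearly_weighted_average
#' @return An object of class `yearly_parameter_series`: a `Y` x d matrix of
#'   per-year parameter vectors (rows are years) plus the config.
#' @export
yearly_parameter_series <- function(estimates, config) {
  rows <- lapply(seq_len(config$Y), function(y)
    yearly_weighted_average(estimates, y, config))
  m <- do.call(rbind, rows)
  rownames(m) <- config$first_year + seq_len(config$Y) - 1L
  structure(list(values = m, config = config),
            class = "yearly_parameter_series")
}

#' @export
print.yearly_parameter_series <- function(x, ...) {
  cat(sprintf("<yearly_parameter_series> %d years x %d parameters (%s..%s)\n",
              nrow(x$values), ncol(x$values),
              rownames(x$values)[1], rownames(x$values)[nrow(x$values)]))
  invisible(x)
}

#' Write a window set to CSV
#'
#' Columns: `window_index`, `kind`, `start_year`, `end_year`, `length`, with
#' years reported as calendar years via the config's `first_year`.
#'
#' @param ws A `window_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  off <- ws$config$first_year - 1L
  d <- data.frame(window_index = ws$windows$index,
                  kind = ws$windows$kind,
                  start_year = ws$windows$start_year + off,
                  end_year = ws$windows$end_year + off,
                  length = ws$windows$length)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
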