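#' Acquisition function specification
#'
#' The acquisition score ranks candidate points under the GP posterior for a
#' minimization problem; larger is more desirable. Three families are
#' supported, with the usual minimization forms: writing
#' `z = (f_best - mu - xi) / sigma`,
#' expected improvement `EI = (f_best - mu - xi) * Phi(z) + sigma * phi(z)`,
#' probability of improvement `PI = Phi(z)`, and the lower-confidence-bound
#' score `-mu + kappa * sigma`.
#'
#' @param family One of `"expected-improvement"`,
#'   `"probability-of-improvement"`, `"lower-confidence-bound"`.
#' @param xi Improvement margin for EI/PI (standardized objective scale).
#' @param kappa Exploration weight for LCB (standardized objective scale).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(family = c("expected-improvement",
                                        "probability-of-improvement",
                                        "lower-confidence-bound"),
                             xi = 0.01, kappa = 2.0) {
  family <- match.arg(family)
  if (xi < 0 || kappa < 0) {
    stop("acquisition_spec: xi and kappa must be non-negative", call. = FALSE)
  }
  structure(list(family = family, xi = xi, kappa = kappa),
            class = "acquisition_spec")
}

#' Acquisition score from posterior mean and standard deviation
#'
#' Closed-form score given predictive `mu`, `sigma` and the incumbent
#' `f_best`, all on one common scale. Vectorized over `mu`/`sigma`. The
#' degenerate `sigma = 0` limits are `EI = max(f_best - mu - xi, 0)` and
#' `PI = 1` if `mu < f_best - xi`, else `0`.
#'
#' @param acq An [acquisition_spec()].
#' @param mu,sigma Predictive mean and standard deviation (`sigma >= 0`).
#' @param f_best Incumbent (best observed) objective value.
#' @return Numeric score vector; larger is better.
#' @export
acquisition_score <- function(acq, mu, sigma, f_best) {
  stopifnot(inherits(acq, "acquisition_spec"), all(sigma >= 0))
  if (acq$family == "lower-confidence-bound") {
    return(-mu + acq$kappa * sigma)
  }
  imp <- f_best - mu - acq$xi
  out <- numeric(length(mu))
  pos <- sigma > 1e-300
  z <- imp[pos] / sigma[pos]
  if (acq$family == "expected-improvement") {
    out[pos] <- imp[pos] * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
    out[!pos] <- pmax(imp[!pos], 0)
  } else {  # probability-of-improvement
    out[pos] <- stats::pnorm(z)
    out[!pos] <- as.numeric(imp[!pos] > 0)
  }
  out
}

#' Acquisition score at a point under a fitted GP
#'
#' Evaluates [acquisition_score()] at the GP posterior of `x`, on the
#' standardized objective scale (where `xi` and `kappa` are defined).
#'
#' @param acq An [acquisition_spec()].
#' @param gp A `gp_posterior` from [fit_gp()].
#' @param x Query point(s) in the unit hypercube (vector or row matrix).
#' @param f_best Incumbent objective on the original scale; defaults to the
#'   best training value seen by the GP.
#' @return Numeric score vector.
#' @export
acquisition_value <- function(acq, gp, x, f_best = NULL) {
  stopifnot(inherits(gp, "gp_posterior"))
  fb <- standardize_incumbent(gp, f_best)
  p <- stats::predict(gp, x, standardized = TRUE)
  acquisition_score(acq, p$mean, p$sd, fb)
}

standardize_incumbent <- function(gp, f_best) {
  if (is.null(f_best)) min(gp$y) else (f_best - gp$y_mean) / gp$y_sd
}

# score and gradient at a single scaled point (standardized scale)
acquisition_with_grad <- function(acq, gp, x, fb) {
  g <- gp_predict_grad(gp, x)
  mu <- g$mean; sd <- g$sd
  if (acq$family == "lower-confidence-bound") {
    return(list(value = -mu + acq$kappa * sd,
                grad = -g$dmean + acq$kappa * g$dsd))
  }
  imp <- fb - mu - acq$xi
  if (sd <= 1e-12) {
    val <- if (acq$family == "expected-improvement") max(imp, 0)
           else as.numeric(imp > 0)
    return(list(value = val, grad = rep(0, length(x))))
  }
  z <- imp / sd
  if (acq$family == "expected-improvement") {
    list(value = imp * stats::pnorm(z) + sd * stats::dnorm(z),
         grad = -stats::pnorm(z) * g$dmean + stats::dnorm(z) * g$dsd)
  } else {
    list(value = stats::pnorm(z),
         grad = stats::dnorm(z) * (-g$dmean - z * g$dsd) / sd)
  }
}

#' Propose the next evaluation point
#'
#' Maximizes the acquisition over the unit hypercube with multi-start bounded
#' quasi-Newton search (L-BFGS-B with analytic gradients), started from
#' `restarts` uniform-random points. Returns the best point found across all
#' runs and start points, so the proposal's acquisition value is never below
#' that of any start point.
#'
#' @param gp A `gp_posterior`.
#' @param acq An [acquisition_spec()].
#' @param restarts Number of random starts, `>= 1`.
#' @param f_best Incumbent objective (original scale); defaults to the GP's
#'   best training value.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return Numeric point in `[0,1]^d` (scaled space).
#' @export
propose_next <- function(gp, acq, restarts = 10, f_best = NULL, maxit = 60) {
  stopifnot(inherits(gp, "gp_posterior"), restarts >= 1)
  d <- ncol(gp$X)
  fb <- standardize_incumbent(gp, f_best)
  starts <- matrix(stats::runif(restarts * d), nrow = restarts)

  best_x <- NULL
  best_v <- -Inf
  any_ok <- FALSE
  for (i in seq_len(restarts)) {
    x0 <- starts[i, ]
    v0 <- acquisition_with_grad(acq, gp, x0, fb)$value
    res <- tryCatch(
      stats::optim(x0,
                   fn = function(x) -acquisition_with_grad(acq, gp, x, fb)$value,
                   gr = function(x) -acquisition_with_grad(acq, gp, x, fb)$grad,
                   method = "L-BFGS-B", lower = rep(0, d), upper = rep(1, d),
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(res)) any_ok <- TRUE
    cand_x <- if (!is.null(res)) res$par else x0
    cand_v <- if (!is.null(res)) -res$value else v0
    if (cand_v > best_v) { best_v <- cand_v; best_x <- cand_x }
    if (v0 > best_v) { best_v <- v0; best_x <- x0 }
  }
  if (!any_ok) {
    warning("propose_next: every quasi-Newton run failed; ",
            "returning the best start point", call. = FALSE)
  }
  pmin(pmax(best_x, 0), 1)
}
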