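#' Gaussian-process kernel specification
#'
#' Covariance family and hyperparameters for a surrogate instance. Inputs are
#' always scaled to the unit hypercube before the kernel is applied, so a
#' single isotropic length scale is shared across parameters.
#'
#' @param family One of `"squared-exponential"`, `"matern32"`, `"matern52"`.
#' @param length_scale Positive length scale, in scaled-input units.
#' @param signal_variance Positive signal variance (standardized-objective
#'   scale).
#' @param tune_by_likelihood If `TRUE` (default), `length_scale` and
#'   `signal_variance` are refit by maximizing the log marginal likelihood at
#'   every [fit_gp()] call, starting from the specified values.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("matern52", "squared-exponential", "matern32"),
                        length_scale = 0.3, signal_variance = 1,
                        tune_by_likelihood = TRUE) {
  family <- match.arg(family)
  if (!is.finite(length_scale) || length_scale <= 0) {
    stop("kernel_spec: length_scale must be > 0", call. = FALSE)
  }
  if (!is.finite(signal_variance) || signal_variance <= 0) {
    stop("kernel_spec: signal_variance must be > 0", call. = FALSE)
  }
  structure(list(family = family, length_scale = length_scale,
                 signal_variance = signal_variance,
                 tune_by_likelihood = isTRUE(tune_by_likelihood)),
            class = "kernel_spec")
}

# Squared Euclidean cross-distances between row-point matrices.
sq_dist <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  d <- matrix(rowSums(X1 * X1), n1, n2) +
    matrix(rowSums(X2 * X2), n1, n2, byrow = TRUE) -
    2 * tcrossprod(X1, X2)
  pmax(d, 0)
}

kernel_matrix <- function(kernel, X1, X2, length_scale = kernel$length_scale,
                          signal_variance = kernel$signal_variance) {
  r <- sqrt(sq_dist(X1, X2))
  switch(kernel$family,
    "squared-exponential" = signal_variance * exp(-0.5 * (r / length_scale)^2),
    "matern32" = {
      s <- sqrt(3) * r / length_scale
      signal_variance * (1 + s) * exp(-s)
    },
    "matern52" = {
      s <- sqrt(5) * r / length_scale
      signal_variance * (1 + s + s^2 / 3) * exp(-s)
    })
}

# d k(x, X) / d x for a single query point x (vector) against rows of X:
# returns an n x d matrix whose row i is the gradient of k(x, X[i, ]).
kernel_cross_grad <- function(kernel, x, X, length_scale = kernel$length_scale,
                              signal_variance = kernel$signal_variance) {
  diff <- sweep(X, 2, x, "-")          # X[i, ] - x
  ls2 <- length_scale^2
  fac <- switch(kernel$family,
    "squared-exponential" = {
      r2 <- rowSums(diff * diff)
      signal_variance * exp(-0.5 * r2 / ls2) / ls2
    },
    "matern32" = {
      s <- sqrt(3) * sqrt(rowSums(diff * diff)) / length_scale
      signal_variance * 3 * exp(-s) / ls2
    },
    "matern52" = {
      s <- sqrt(5) * sqrt(rowSums(diff * diff)) / length_scale
      signal_variance * (5 / 3) * (1 + s) * exp(-s) / ls2
    })
  # d k / d x = fac * (X[i, ] - x): kernels decrease away from x.
  diff * fac
}

neg_log_marglik <- function(log_par, kernel, X, y, jitter, want_grad = FALSE) {
  ls <- exp(log_par[1]); sv <- exp(log_par[2])
  r <- sqrt(sq_dist(X, X))
  if (kernel$family == "squared-exponential") {
    Kf <- sv * exp(-0.5 * (r / ls)^2)
    dK_ls <- Kf * (r / ls)^2                 # d K / d log(ls)
  } else if (kernel$family == "matern32") {
    s <- sqrt(3) * r / ls
    e <- exp(-s)
    Kf <- sv * (1 + s) * e
    dK_ls <- sv * s^2 * e
  } else {
    s <- sqrt(5) * r / ls
    e <- exp(-s)
    Kf <- sv * (1 + s + s^2 / 3) * e
    dK_ls <- sv * s^2 * (1 + s) / 3 * e
  }
  K <- Kf
  diag(K) <- diag(K) + jitter
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    return(if (want_grad) list(value = 1e10, grad = c(0, 0)) else 1e10)
  }
  alpha <- backsolve(L, forwardsolve(t(L), y))
  val <- as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(L))) +
                      0.5 * length(y) * log(2 * pi))
  if (!want_grad) return(val)
  # d(-logL)/d theta = 0.5 tr((K^-1 - alpha alpha^T) dK/dtheta)
  Kinv <- chol2inv(L)
  A <- Kinv - tcrossprod(alpha)
  list(value = val,
       grad = c(0.5 * sum(A * dK_ls), 0.5 * sum(A * Kf)))
}

#' Fit a Gaussian-process surrogate
#'
#' Fits GP regression to evaluation records. Inputs must already live in the
#' unit hypercube (`x_scaled`); objective values are standardized internally
#' to zero mean and unit variance. Near-duplicate inputs (within `dedup_tol`
#' in scaled space) are merged with a warning, averaging their objectives. If
#' the Cholesky factorization fails, the noise jitter is escalated by decades
#' up to `max_jitter`.
#'
#' @param records A list of evaluation records, each with elements `x_scaled`
#'   (numeric in `[0,1]^d`) and `f` (objective value), e.g. from [run_pbo()]
#'   traces; alternatively a list with matrix `X` and vector `f`.
#' @param kernel A [kernel_spec()].
#' @param jitter Initial diagonal jitter (standardized scale).
#' @param max_jitter Cap for jitter escalation.
#' @param dedup_tol Merge tolerance for duplicate inputs (scaled space).
#' @return An object of class `gp_posterior` with predictive accessors via
#'   [predict.gp_posterior()].
#' @export
fit_gp <- function(records, kernel, jitter = 1e-6, max_jitter = 1e-2,
                   dedup_tol = 1e-8) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (is.list(records) && !is.null(records$X)) {
    X <- as.matrix(records$X); f <- as.numeric(records$f)
  } else {
    X <- do.call(rbind, lapply(records, function(r) r$x_scaled))
    f <- vapply(records, function(r) as.numeric(r$f), numeric(1))
  }
  stopifnot(nrow(X) == length(f))

  # merge near-duplicates: average their objective values
  keep <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(X))[-1]) {
    if (!keep[i]) next
    prev <- which(keep[seq_len(i - 1L)])
    d2 <- colSums((t(X[prev, , drop = FALSE]) - X[i, ])^2)
    hit <- prev[d2 < dedup_tol^2]
    if (length(hit)) {
      f[hit[1]] <- mean(c(f[hit[1]], f[i]))
      keep[i] <- FALSE
    }
  }
  if (!all(keep)) {
    warning("fit_gp: merged ", sum(!keep), " duplicate input(s)", call. = FALSE)
    X <- X[keep, , drop = FALSE]; f <- f[keep]
  }
  if (nrow(X) < 2L) stop("fit_gp: need >= 2 distinct inputs", call. = FALSE)

  y_mean <- mean(f)
  y_sd <- stats::sd(f)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  y <- (f - y_mean) / y_sd

  if (kernel$tune_by_likelihood) {
    opt <- stats::optim(
      log(c(kernel$length_scale, kernel$signal_variance)),
      fn = function(p) neg_log_marglik(p, kernel, X, y, jitter),
      gr = function(p) neg_log_marglik(p, kernel, X, y, jitter,
                                       want_grad = TRUE)$grad,
      method = "L-BFGS-B",
      lower = log(c(1e-2, 1e-3)), upper = log(c(1e2, 1e3)),
      control = list(maxit = 25))
    kernel$length_scale <- exp(opt$par[1])
    kernel$signal_variance <- exp(opt$par[2])
  }

  j <- jitter
  repeat {
    K <- kernel_matrix(kernel, X, X)
    diag(K) <- diag(K) + j
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (!is.null(L)) break
    j <- j * 10
    if (j > max_jitter) {
      stop("fit_gp: covariance singular even at jitter ", max_jitter,
           call. = FALSE)
    }
  }
  Lt <- t(L)
  alpha <- backsolve(L, forwardsolve(Lt, y))

  structure(list(X = X, y = y, y_mean = y_mean, y_sd = y_sd,
                 kernel = kernel, jitter = j, L = L, Lt = Lt, alpha = alpha),
            class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf(
    "<gp_posterior> %d points, d = %d, kernel %s (ls = %.3g, sv = %.3g), jitter %.1g\n",
    nrow(x$X), ncol(x$X), x$kernel$family, x$kernel$length_scale,
    x$kernel$signal_variance, x$jitter))
  invisible(x)
}

#' Predict from a fitted GP posterior
#'
#' @param object A `gp_posterior` from [fit_gp()].
#' @param newdata Matrix of query points (rows) in the unit hypercube, or a
#'   single point as a vector.
#' @param standardized If `TRUE`, return mean/sd on the internal standardized
#'   objective scale; otherwise on the original objective scale.
#' @param ... Unused.
#' @return A list with numeric vectors `mean` and `sd`.
#' @export
predict.gp_posterior <- function(object, newdata, standardized = FALSE, ...) {
  Xs <- as_point_matrix(newdata, ncol(object$X))
  Ks <- kernel_matrix(object$kernel, Xs, object$X)
  mu <- drop(Ks %*% object$alpha)
  V <- forwardsolve(object$Lt, t(Ks))
  var <- pmax(object$kernel$signal_variance - colSums(V * V), 0)
  sd <- sqrt(var)
  if (!standardized) {
    mu <- object$y_mean + object$y_sd * mu
    sd <- object$y_sd * sd
  }
  list(mean = mu, sd = sd)
}

# Mean/sd and their gradients at a single scaled point, standardized scale.
# Kernel values and gradients share one difference matrix for speed: this is
# the inner loop of acquisition maximization.
gp_predict_grad <- function(gp, x) {
  x <- as.numeric(x)
  kern <- gp$kernel
  ls <- kern$length_scale; sv <- kern$signal_variance
  diff <- gp$X - matrix(x, nrow(gp$X), length(x), byrow = TRUE)  # X[i,] - x
  r2 <- rowSums(diff * diff)
  if (kern$family == "squared-exponential") {
    k <- sv * exp(-0.5 * r2 / ls^2)
    fac <- k / ls^2
  } else if (kern$family == "matern32") {
    s <- sqrt(3 * r2) / ls
    e <- exp(-s)
    k <- sv * (1 + s) * e
    fac <- sv * 3 * e / ls^2
  } else {
    s <- sqrt(5 * r2) / ls
    e <- exp(-s)
    k <- sv * (1 + s + s^2 / 3) * e
    fac <- sv * (5 / 3) * (1 + s) * e / ls^2
  }
  mu <- sum(k * gp$alpha)
  v <- forwardsolve(gp$Lt, k)
  var <- max(sv - sum(v * v), 0)
  sd <- sqrt(var)
  dK <- diff * fac                                      # m x d
  dmu <- drop(crossprod(dK, gp$alpha))
  dv <- forwardsolve(gp$Lt, dK)                         # m x d
  dvar <- -2 * drop(crossprod(dv, v))
  dsd <- if (sd > 1e-12) dvar / (2 * sd) else rep(0, length(x))
  list(mean = mu, sd = sd, dmean = dmu, dsd = dsd)
}
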