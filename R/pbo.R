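#' Default roster of surrogate instances
#'
#' Heterogeneous (acquisition, kernel) pairs for the parallel optimizer: the
#' three acquisition families crossed with the Matern-5/2 and
#' squared-exponential kernels, truncated or recycled to `N`.
#'
#' @param N Number of instances.
#' @param xi,kappa Acquisition parameters passed to [acquisition_spec()].
#' @return A list of `N` lists, each with elements `acquisition` and `kernel`.
#' @export
default_instances <- function(N = 6, xi = 0.01, kappa = 2.0) {
  fams <- c("expected-improvement", "probability-of-improvement",
            "lower-confidence-bound")
  kerns <- c("matern52", "squared-exponential")
  roster <- list()
  for (k in kerns) for (a in fams) {
    roster[[length(roster) + 1L]] <- list(
      acquisition = acquisition_spec(a, xi = xi, kappa = kappa),
      kernel = kernel_spec(k))
  }
  roster[((seq_len(N) - 1L) %% length(roster)) + 1L]
}

#' Parallel Bayesian optimization configuration
#'
#' @param N Number of parallel surrogate instances (`>= 1`).
#' @param T Maximum number of iterations (`>= 1`); each iteration evaluates
#'   one proposal per instance.
#' @param instances List of `N` `(acquisition, kernel)` pairs as produced by
#'   [default_instances()].
#' @param init_design_size Number of initial Latin-hypercube evaluations
#'   shared by all instances; default `max(10, 2d)` chosen at run time.
#' @param restarts Multi-start count for the acquisition maximizer.
#' @param improvement_threshold Optional early-stop tolerance: stop when the
#'   incumbent improves by less than this over one iteration. `NULL` (default)
#'   disables it, so `T` governs.
#' @param seed Master seed; all randomness (design, proposal restarts) derives
#'   from it, so runs are reproducible and instances compose deterministically.
#' @return An object of class `pbo_config`.
#' @export
pbo_config <- function(N = 6, T = 30, instances = default_instances(N),
                       init_design_size = NULL, restarts = 10,
                       improvement_threshold = NULL, seed = 1L) {
  N <- as.integer(N); T <- as.integer(T)
  if (N < 1L || T < 1L) stop("pbo_config: need N >= 1 and T >= 1", call. = FALSE)
  if (length(instances) != N) {
    stop("pbo_config: need exactly N = ", N, " instances (got ",
         length(instances), ")", call. = FALSE)
  }
  if (!is.null(init_design_size) && init_design_size < 2) {
    stop("pbo_config: init_design_size must be >= 2", call. = FALSE)
  }
  structure(list(N = N, T = T, instances = instances,
                 init_design_size = init_design_size,
                 restarts = as.integer(restarts),
                 improvement_threshold = improvement_threshold,
                 seed = as.integer(seed)),
            class = "pbo_config")
}

# deterministic sub-seed derivation, kept inside 32-bit range
derive_seed <- function(master, a = 0, b = 0) {
  as.integer((as.numeric(master) * 1000003 + a * 10007 + b * 101 + 12345) %%
               2147483647)
}

eval_objective <- function(objective, theta) {
  val <- tryCatch(objective(theta), error = function(e) e)
  if (inherits(val, "error") || !is.finite(val)) NULL else as.numeric(val)
}

#' Run parallel Bayesian optimization
#'
#' Minimizes a black-box objective over a bounded box with `N` heterogeneous
#' Bayesian-optimization instances that share one evaluation pool. After an
#' initial Latin-hypercube design, each iteration has every instance refit its
#' Gaussian process on the full shared pool and propose one point by
#' maximizing its own acquisition; all `N` proposals are then evaluated and
#' appended to the pool, and the incumbent is updated. Total objective calls
#' are `init_design_size + N * iterations`.
#'
#' @param objective Function `theta -> loss` (finite on any in-bounds point;
#'   exceptions are tolerated: the instance re-proposes once, then falls back
#'   to a random in-bounds point).
#' @param bounds 2 x d bounds matrix (rows `lower`, `upper`) or a list of
#'   [parameter_spec()]s.
#' @param config A [pbo_config()].
#' @return An object of class `pbo_trace` with the evaluation records
#'   (`theta`, `X` scaled, `f`, `instance`, `iteration`), the per-iteration
#'   incumbent objective and point, and the stop reason.
#' @examples
#' obj <- function(x) sum((x - 0.3)^2)
#' b <- rbind(lower = c(0, 0), upper = c(1, 1))
#' tr <- run_pbo(obj, b, pbo_config(N = 3, T = 5, instances = default_instances(3),
#'                                  seed = 7))
#' min(tr$f)
#' @export
run_pbo <- function(objective, bounds, config) {
  stopifnot(inherits(config, "pbo_config"))
  bounds <- as_bounds(bounds)
  d <- ncol(bounds)
  m0 <- if (is.null(config$init_design_size)) max(10L, 2L * d)
        else as.integer(config$init_design_size)

  set.seed(derive_seed(config$seed, 0, 0))
  U <- lhs::randomLHS(m0, d)
  X <- matrix(numeric(0), ncol = d)
  theta <- matrix(numeric(0), ncol = d, dimnames = list(NULL, colnames(bounds)))
  f <- numeric(0)
  instance <- integer(0)
  iteration <- integer(0)

  add_record <- function(u, it, inst) {
    th <- drop(unit_to_scale(u, bounds))
    val <- eval_objective(objective, th)
    if (is.null(val)) return(FALSE)
    X <<- rbind(X, u); theta <<- rbind(theta, th)
    f <<- c(f, val); instance <<- c(instance, inst); iteration <<- c(iteration, it)
    TRUE
  }

  for (i in seq_len(m0)) {
    if (!add_record(U[i, ], 0L, NA_integer_)) {
      # degenerate objective on a design point: retry at a random point
      add_record(stats::runif(d), 0L, NA_integer_)
    }
  }
  if (length(f) < 2L) {
    stop("run_pbo: objective failed on the initial design", call. = FALSE)
  }

  inc_val <- min(f)
  inc_idx <- which.min(f)
  incumbent_objective <- inc_val
  incumbent_theta <- theta[inc_idx, , drop = FALSE]
  stop_reason <- "max_iterations"
  iters_run <- 0L

  for (t in seq_len(config$T)) {
    pool <- list(X = X, f = f)
    proposals <- matrix(NA_real_, nrow = config$N, ncol = d)
    for (i in seq_len(config$N)) {
      inst <- config$instances[[i]]
      set.seed(derive_seed(config$seed, t, i))
      gp <- fit_gp(pool, inst$kernel)
      u <- propose_next(gp, inst$acquisition, restarts = config$restarts)
      # replace proposals duplicating the pool or this iteration's batch
      seen <- rbind(X, proposals[seq_len(i - 1L), , drop = FALSE])
      if (min(colSums((t(seen) - u)^2)) < (1e-8)^2) {
        message("run_pbo: instance ", i, " proposed a duplicate at iteration ",
                t, "; replaced by a random point")
        u <- stats::runif(d)
      }
      proposals[i, ] <- u
    }
    for (i in seq_len(config$N)) {
      if (!add_record(proposals[i, ], t, i)) {
        # objective failed: re-propose once, then fall back to a random point
        set.seed(derive_seed(config$seed, t, i + 1000L))
        gp <- fit_gp(list(X = X, f = f), config$instances[[i]]$kernel)
        u2 <- propose_next(gp, config$instances[[i]]$acquisition,
                           restarts = config$restarts)
        if (!add_record(u2, t, i)) {
          message("run_pbo: objective failed twice for instance ", i,
                  " at iteration ", t, "; using a random point")
          if (!add_record(stats::runif(d), t, i)) {
            message("run_pbo: record skipped for instance ", i,
                    " at iteration ", t)
          }
        }
      }
    }
    iters_run <- t
    new_inc <- min(f)
    improvement <- inc_val - new_inc
    if (new_inc < inc_val) {
      inc_val <- new_inc
      inc_idx <- which.min(f)
    }
    incumbent_objective <- c(incumbent_objective, inc_val)
    incumbent_theta <- rbind(incumbent_theta, theta[inc_idx, , drop = FALSE])
    if (!is.null(config$improvement_threshold) &&
        improvement < config$improvement_threshold) {
      stop_reason <- "improvement_threshold"
      break
    }
  }

  structure(list(theta = theta, X = X, f = f, instance = instance,
                 iteration = iteration,
                 incumbent_objective = incumbent_objective,
                 incumbent_theta = incumbent_theta,
                 best_theta = theta[which.min(f), ],
                 best_objective = min(f),
                 iterations_run = iters_run,
                 init_design_size = m0,
                 stop_reason = stop_reason,
                 config = config, bounds = bounds),
            class = "pbo_trace")
}

#' Run single-instance Bayesian optimization (baseline)
#'
#' Classic BO: one surrogate instance, one evaluation per iteration. This is
#' the comparison baseline for [run_pbo()]; with the same seed, `run_pbo`
#' with `N = 1` and the same instance produces an identical trace.
#'
#' @inheritParams run_pbo
#' @param acq An [acquisition_spec()].
#' @param kernel A [kernel_spec()].
#' @param T Number of iterations.
#' @param init_design_size Initial design size (`NULL` for `max(10, 2d)`).
#' @param restarts Acquisition-maximizer restarts.
#' @param seed Master seed.
#' @return A `pbo_trace`.
#' @export
run_bo <- function(objective, bounds, acq = acquisition_spec(),
                   kernel = kernel_spec(), T = 30, init_design_size = NULL,
                   restarts = 10, seed = 1L) {
  cfg <- pbo_config(N = 1L, T = T,
                    instances = list(list(acquisition = acq, kernel = kernel)),
                    init_design_size = init_design_size, restarts = restarts,
                    seed = seed)
  run_pbo(objective, bounds, cfg)
}

#' @export
print.pbo_trace <- function(x, ...) {
  cat(sprintf(
    "<pbo_trace> %d evaluations (%d init + %d x %d iterations), incumbent %.6g, stop: %s\n",
    length(x$f), x$init_design_size, x$config$N, x$iterations_run,
    x$best_objective, x$stop_reason))
  invisible(x)
}

#' Serialize a PBO trace
#'
#' `write_trace_csv` writes one row per evaluation (iteration, instance,
#' parameter columns, objective, incumbent-so-far); `write_trace_meta` writes
#' the run metadata (configuration echo, seed, stop reason) as JSON.
#'
#' @param trace A `pbo_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pbo_trace"))
  d <- as.data.frame(trace$theta)
  if (is.null(colnames(trace$theta))) {
    names(d) <- paste0("x", seq_len(ncol(trace$theta)))
  }
  d <- cbind(iteration = trace$iteration, instance = trace$instance, d,
             objective = trace$f, incumbent = cummin(trace$f))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_trace_meta <- function(trace, path) {
  stopifnot(inherits(trace, "pbo_trace"))
  cfg <- trace$config
  meta <- list(
    N = cfg$N, T = cfg$T, seed = cfg$seed,
    init_design_size = trace$init_design_size,
    restarts = cfg$restarts,
    improvement_threshold = cfg$improvement_threshold,
    instances = lapply(cfg$instances, function(i)
      list(acquisition = i$acquisition$family, xi = i$acquisition$xi,
           kappa = i$acquisition$kappa, kernel = i$kernel$family)),
    iterations_run = trace$iterations_run,
    evaluations = length(trace$f),
    best_objective = trace$best_objective,
    stop_reason = trace$stop_reason)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
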