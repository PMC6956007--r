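# Bounded maximum-likelihood estimation of theta = [a, b, c, d, F].

#' Default estimation bounds
#'
#' Lower bounds are zero on every coordinate (all model parameters are
#' non-negative); upper bounds default to 1 for the ODE coefficients and
#' 200 ms^-1 for the maximum rate, enclosing the nominal parameter
#' regime with wide margin.
#'
#' @return List with numeric `lower` and `upper` of length 5.
#' @export
default_bounds <- function() {
  list(lower = c(a = 0, b = 0, c = 0, d = 0, F = 1e-3),
       upper = c(a = 1, b = 1, c = 1, d = 1, F = 200))
}

#' Maximum-likelihood parameter estimation
#'
#' Maximises the joint point-process log-likelihood of a dataset over
#' the bounded parameter box with a quasi-Newton method (`L-BFGS-B`),
#' using forward-difference gradients (relative step `1e-6`, absolute
#' floor `1e-8`).  The initial guess defaults to a uniform draw inside
#' the bounds from R's current random stream; pass `init` to fix it.
#'
#' @param dataset An [fn_dataset()].
#' @param bounds List with `lower`/`upper` length-5 vectors; defaults to
#'   [default_bounds()].  Setting `lower[j] == upper[j]` clamps that
#'   coordinate exactly (useful for profile-style fits).
#' @param init Initial [fn_params] (must lie within bounds), or `NULL`
#'   for a random interior point (draws whose objective is infeasible —
#'   e.g. the integration diverges there — are rejected and redrawn).
#' @param control Optional list: `maxit` (default 500), `factr`
#'   (default 1e4), `pgtol` (default 1e-8), `trace_calls` (logical,
#'   record every objective evaluation point).
#' @return An object of class `"fn_fit"`: `theta_hat` ([fn_params]),
#'   `logLik`, `converged`, `counts`, `message`, `init`, `bounds`,
#'   `elapsed` (wall seconds) and, if requested, `calls` (matrix of
#'   evaluated parameter points).
#' @examples
#' \donttest{
#' set.seed(1)
#' ds <- generate_dataset(fn_params(), fn_scenario(Nit = 10), seed = 1)
#' fit <- fn_estimate(ds, init = fn_params())
#' fit$theta_hat
#' }
#' @export
fn_estimate <- function(dataset, bounds = default_bounds(), init = NULL,
                        control = list()) {
  stopifnot(inherits(dataset, "fn_dataset"))
  lower <- as.numeric(bounds$lower); upper <- as.numeric(bounds$upper)
  if (length(lower) != 5L || length(upper) != 5L || any(lower < 0) ||
      any(upper < lower) || all(upper == lower))
    stop("bounds must be length-5 with 0 <= lower <= upper, at least one free")
  free <- upper > lower   # equal bounds clamp a coordinate exactly
  maxit <- control$maxit %||% 500L
  factr <- control$factr %||% 1e4
  pgtol <- control$pgtol %||% 1e-8
  trace_calls <- isTRUE(control$trace_calls)

  calls <- if (trace_calls) new.env() else NULL
  if (trace_calls) calls$pts <- list()
  negll <- function(theta) {
    v <- cpp_joint_negll(theta, dataset$stim_mat, dataset$spike_idx,
                         dataset$offsets, dataset$grid$dt, 0, 0,
                         .fn_vclamp, .fn_blowup, .fn_bigval)
    if (trace_calls) calls$pts[[length(calls$pts) + 1L]] <- theta
    v
  }
  if (is.null(init)) {
    # reject infeasible draws (diverged integration gives a flat
    # penalty with no gradient information) and redraw
    for (try in 1:50) {
      init <- lower + stats::runif(5) * (upper - lower)
      if (negll(init) < .fn_bigval) break
      if (try == 50)
        stop("estimation failed: no feasible random initial guess in 50 draws")
    }
  } else {
    init <- as.numeric(init)
    if (any(init < lower) || any(init > upper))
      stop("initial guess outside bounds")
  }
  # forward differences, stepping inward at the upper bound
  grad <- function(theta) {
    f0 <- negll(theta)
    g <- numeric(5)
    for (j in which(free)) {
      h <- max(1e-6 * abs(theta[j]), 1e-8)
      th <- theta
      if (theta[j] + h <= upper[j]) {
        th[j] <- theta[j] + h
        g[j] <- (negll(th) - f0) / h
      } else {
        th[j] <- theta[j] - h
        g[j] <- (f0 - negll(th)) / h
      }
    }
    g
  }

  t0 <- proc.time()[["elapsed"]]
  opt <- stats::optim(init, fn = negll, gr = grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = factr,
                                     pgtol = pgtol))
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.finite(opt$value) || opt$value >= .fn_bigval)
    stop("estimation failed: no finite objective value found (final = ",
         opt$value, ")")
  structure(list(
    theta_hat = as_fn_params(pmin(pmax(opt$par, lower), upper)),
    logLik = -opt$value,
    converged = opt$convergence == 0L,
    counts = opt$counts,
    message = opt$message,
    init = as_fn_params(init),
    bounds = list(lower = lower, upper = upper),
    elapsed = elapsed,
    calls = if (trace_calls) do.call(rbind, calls$pts) else NULL),
    class = "fn_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fn_fit <- function(x, ...) {
  cat("FitzHugh-Nagumo ML fit\n")
  print(unclass(x$theta_hat))
  cat(sprintf("log-likelihood %.4f, %sconverged (%d objective calls, %.1fs)\n",
              x$logLik, if (x$converged) "" else "NOT ",
              x$counts[["function"]], x$elapsed))
  invisible(x)
}

#' Serialize an estimation result to JSON
#'
#' @param fit An `fn_fit` from [fn_estimate()].
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fn_fit"))
  jsonlite::write_json(
    list(theta_hat = as.list(unclass(fit$theta_hat)),
         logLik = fit$logLik, converged = fit$converged,
         init = as.list(unclass(fit$init)),
         bounds = fit$bounds, elapsed_s = fit$elapsed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
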