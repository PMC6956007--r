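# FitzHugh-Nagumo dynamics, sigmoid rate map and fixed-step integration.

# V excursions are clamped to +/- .fn_vclamp before exponentiation in the
# sigmoid; exp(500) is representable, so the rate never under- or
# overflows to an exact 0 or F.
.fn_vclamp <- 500
# |V| or |W| beyond this bound aborts integration: nominal trajectories
# stay O(10), so 1e6 unambiguously flags an infeasible parameter draw.
.fn_blowup <- 1e6

#' FitzHugh-Nagumo state derivatives
#'
#' Right-hand side of the two-variable FitzHugh-Nagumo system
#' \deqn{\dot V = V - d V^3 - W + I, \qquad \dot W = c V + a - b W,}
#' where `V` is the membrane-potential-like variable, `W` the lumped
#' recovery variable and `I` the stimulus current.
#'
#' @param state Numeric length-2 vector `c(V, W)`.
#' @param params An [fn_params] vector (only `a`, `b`, `c`, `d` are used).
#' @param I Stimulus current (scalar).
#' @return Named numeric vector `c(dV, dW)`.
#' @examples
#' fn_derivatives(c(0, 0), fn_params())   # (0, a)
#' @export
fn_derivatives <- function(state, params, I = 0) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("state must be a finite numeric vector c(V, W)")
  if (!is.finite(I)) stop("stimulus current must be finite")
  params <- as_fn_params(params)
  V <- state[[1]]; W <- state[[2]]
  c(dV = V - params[["d"]] * V^3 - W + I,
    dW = params[["c"]] * V + params[["a"]] - params[["b"]] * W)
}

#' Sigmoid firing-rate map
#'
#' Maps membrane potential to instantaneous firing rate through a scaled
#' logistic sigmoid, \eqn{r = F / (1 + e^{-V})}.  The rate is strictly
#' between 0 and `F` for any finite `V`; `V` is clamped to +/- 500
#' before exponentiation so the map never under- or overflows.
#'
#' @param V Membrane potential value(s).
#' @param F Maximum firing rate, ms^-1.
#' @return Rate value(s), same length as `V`, in ms^-1.
#' @examples
#' firing_rate(0, 100)        # 50: sigmoid midpoint
#' firing_rate(-log(3), 100)  # 25
#' @export
firing_rate <- function(V, F) {
  if (!is.numeric(F) || length(F) != 1L || !is.finite(F) || F <= 0)
    stop("F must be a positive scalar")
  V <- pmin(pmax(V, -.fn_vclamp), .fn_vclamp)
  F / (1 + exp(-V))
}

#' Integrate the model to a firing-rate trajectory
#'
#' Integrates the FitzHugh-Nagumo system with a fixed-step explicit
#' solver (forward Euler by default; classical RK4 with the stimulus
#' held constant over each step as an option) and maps the membrane
#' potential through [firing_rate()] at every grid node.
#'
#' @param params An [fn_params] vector.
#' @param stim Per-node stimulus current, length `grid$n` (a scalar is
#'   recycled).
#' @param grid A [time_grid].
#' @param init Initial state `c(V, W)`; default `c(0, 0)`, the
#'   convention used for every likelihood evaluation.
#' @param method `"euler"` (default) or `"rk4"`.
#' @return An object of class `"rate_trajectory"`: list with `grid`,
#'   `rate` (ms^-1, length `grid$n`), `V`, `W`.
#' @examples
#' g <- time_grid(Tf = 5)
#' tr <- integrate_rate(fn_params(), 0, g)
#' range(tr$rate)
#' @export
integrate_rate <- function(params, stim, grid, init = c(0, 0),
                           method = c("euler", "rk4")) {
  method <- match.arg(method)
  params <- as_fn_params(params)
  stopifnot(inherits(grid, "time_grid"))
  if (length(stim) == 1L) stim <- rep(as.numeric(stim), grid$n)
  if (length(stim) != grid$n)
    stop("stimulus waveform length must equal the grid node count")
  if (any(!is.finite(stim))) stop("stimulus waveform contains non-finite values")
  if (length(init) != 2L || any(!is.finite(init)))
    stop("initial state must be a finite c(V, W)")
  res <- cpp_fn_integrate(unclass(params)[1:4], stim, grid$dt,
                          init[[1]], init[[2]], .fn_blowup,
                          method == "rk4")
  if (res$diverged_at > 0)
    stop(sprintf("integration diverged at step %d (|V| or |W| > %g)",
                 res$diverged_at, .fn_blowup))
  structure(list(grid = grid,
                 rate = firing_rate(res$V, params[["F"]]),
                 V = res$V, W = res$W),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("rate trajectory: %d nodes over %g ms, rate in [%.4g, %.4g] ms^-1\n",
              x$grid$n, x$grid$Tf, min(x$rate), max(x$rate)))
  invisible(x)
}
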