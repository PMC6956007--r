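#' Neuron parameter vector
#'
#' Constructs and validates the five-parameter vector
#' \eqn{\theta = [a, b, c, d, F]} of the firing-rate-modified
#' FitzHugh-Nagumo neuron.  `a`, `b`, `c`, `d` are the dimensionless ODE
#' coefficients (see [fn_derivatives()]); `F` is the maximum firing rate
#' in spikes per millisecond (see [firing_rate()]).
#'
#' All of `a`, `b`, `c`, `d` must be non-negative and `F` strictly
#' positive: the estimator uses a zero lower bound on every coordinate,
#' so the parameter space is the non-negative orthant.
#'
#' @param a,b,c,d Non-negative ODE coefficients.  `d` scales the cubic
#'   term (classically 1/3, treated as free here).
#' @param F Maximum firing rate, ms^-1; must be > 0.
#' @return A named numeric vector of class `"fn_params"`.
#' @examples
#' fn_params()           # nominal values used throughout the examples
#' fn_params(F = 50)
#' @export
fn_params <- function(a = 0.08, b = 0.056, c = 0.064, d = 0.333, F = 100) {
  theta <- c(a = a, b = b, c = c, d = d, F = F)
  validate_fn_params(theta)
  structure(theta, class = "fn_params")
}

validate_fn_params <- function(theta) {
  if (length(theta) != 5L || !is.numeric(theta))
    stop("parameter vector must be numeric of length 5 [a, b, c, d, F]")
  if (any(!is.finite(theta)))
    stop("parameter vector contains non-finite values")
  if (any(theta[1:4] < 0))
    stop("a, b, c, d must be non-negative")
  if (theta[5] <= 0)
    stop("F (maximum firing rate) must be positive")
  invisible(theta)
}

#' @export
print.fn_params <- function(x, ...) {
  cat("FitzHugh-Nagumo parameters (F in ms^-1):\n")
  print(unclass(x), ...)
  invisible(x)
}

as_fn_params <- function(x) {
  if (inherits(x, "fn_params")) return(x)
  x <- as.numeric(x)
  validate_fn_params(x)
  structure(stats::setNames(x, c("a", "b", "c", "d", "F")),
            class = "fn_params")
}

#' Integration and binning grid
#'
#' A fixed-step time grid over one trial window.  The window `[0, Tf]`
#' is divided into `Tf/dt` bins; all quantities (stimulus, membrane
#' state, firing rate, spike probabilities) live on the left endpoints
#' `0, dt, ..., Tf - dt`, so that summing a rate over the nodes times
#' `dt` is the left Riemann sum of its integral over the window.
#'
#' @param Tf Window duration in ms (default 30).
#' @param dt Step in ms (default 0.01, i.e. 10 microseconds).  `Tf` must
#'   be an integer multiple of `dt` to within 1 part in 1e9.
#' @return An object of class `"time_grid"` with elements `Tf`, `dt` and
#'   `n` (node count).
#' @examples
#' g <- time_grid()
#' g$n   # 3000 nodes
#' @export
time_grid <- function(Tf = 30, dt = 0.01) {
  if (!is.numeric(Tf) || !is.numeric(dt) || Tf <= 0 || dt <= 0)
    stop("Tf and dt must be positive")
  n_real <- Tf / dt
  n <- round(n_real)
  if (abs(n_real - n) > 1e-9 * n_real)
    stop("Tf must be an integer multiple of dt")
  structure(list(Tf = Tf, dt = dt, n = as.integer(n)), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time grid: Tf = %g ms, dt = %g ms (%d nodes)\n",
              x$Tf, x$dt, x$n))
  invisible(x)
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @return `grid_times()` returns the node times `0, dt, ..., Tf - dt`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  seq(0, by = grid$dt, length.out = grid$n)
}
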