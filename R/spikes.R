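# Inhomogeneous-Poisson spike-train simulation.
#
# Two independent simulators target the same point process: the local
# Bernoulli approximation on the integration grid (the primary,
# generative route) and thinning (an exact IPP sampler used to
# cross-validate the first).

#' Spike train constructor
#'
#' An ordered vector of spike times (ms) within a trial window, with no
#' amplitude information.
#'
#' @param times Strictly increasing spike times in `[0, Tf]`.
#' @param Tf Window length in ms.
#' @return Numeric vector of class `"spike_train"` with attribute `Tf`.
#' @export
spike_train <- function(times, Tf) {
  times <- as.numeric(times)
  if (length(times) && (is.unsorted(times, strictly = TRUE) ||
                        times[1] < 0 || times[length(times)] > Tf))
    stop("spike times must be strictly increasing within [0, Tf]")
  structure(times, Tf = Tf, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes in [0, %g] ms\n",
              length(x), attr(x, "Tf")))
  invisible(x)
}

#' Local-Bernoulli spike sampling
#'
#' Discretises the inhomogeneous Poisson process on the rate
#' trajectory's grid: bin `i` fires independently with probability
#' `p_i = min(r(t_i) * dt, 1)`, i.e. a spike is emitted at the node time
#' `t_i` whenever `p_i > x` for `x ~ U[0, 1]`.  At most one spike per
#' bin.  Uses R's current random stream.
#'
#' @param rate A `rate_trajectory` from [integrate_rate()] (or
#'   [constant_rate()]).
#' @return A [spike_train()] of node times.
#' @seealso [sample_spikes_thinning()] for the exact sampler.
#' @export
sample_spikes_bernoulli <- function(rate) {
  stopifnot(inherits(rate, "rate_trajectory"))
  p <- rate$rate * rate$grid$dt
  if (any(p > 1)) {
    warning("r * dt exceeds 1 in ", sum(p > 1),
            " bins; Bernoulli approximation degraded (probability clipped at 1)")
    p <- pmin(p, 1)
  }
  fired <- p > stats::runif(rate$grid$n)
  spike_train(grid_times(rate$grid)[fired], rate$grid$Tf)
}

#' Thinning spike sampling
#'
#' Exact inhomogeneous-Poisson simulation: homogeneous Poisson
#' candidates at the bound `r* = max rate` on `[0, Tf]`, each retained
#' with probability `r(t)/r*`, with the rate linearly interpolated
#' between grid nodes.  Serves as an independent cross-check of
#' [sample_spikes_bernoulli()].
#'
#' @inheritParams sample_spikes_bernoulli
#' @param rate_bound Upper bound for the candidate rate; defaults to the
#'   trajectory maximum.
#' @return A [spike_train()].
#' @export
sample_spikes_thinning <- function(rate, rate_bound = NULL) {
  stopifnot(inherits(rate, "rate_trajectory"))
  Tf <- rate$grid$Tf
  rstar <- if (is.null(rate_bound)) max(rate$rate) else rate_bound
  if (rstar <= 0) return(spike_train(numeric(0), Tf))
  if (rstar < max(rate$rate)) stop("rate_bound must dominate the trajectory")
  ncand <- stats::rpois(1, rstar * Tf)
  if (ncand == 0) return(spike_train(numeric(0), Tf))
  cand <- sort(stats::runif(ncand, 0, Tf))
  r_at <- stats::approx(grid_times(rate$grid), rate$rate, xout = cand,
                        rule = 2)$y
  keep <- stats::runif(ncand) < r_at / rstar
  spike_train(unique(cand[keep]), Tf)
}

#' Constant-rate trajectory helper
#'
#' Builds a `rate_trajectory` with a constant rate, mainly for
#' homogeneous-Poisson checks and examples.
#'
#' @param r Rate in ms^-1 (0 < r).
#' @param grid A [time_grid].
#' @export
constant_rate <- function(r, grid) {
  stopifnot(inherits(grid, "time_grid"), is.numeric(r), r > 0)
  structure(list(grid = grid, rate = rep(as.numeric(r), grid$n),
                 V = NULL, W = NULL),
            class = "rate_trajectory")
}

#' Superimpose spike trains from consecutive segments
#'
#' Concatenates spike trains, offsetting each train's times by its
#' segment index times the common window length, as used to pool
#' independent segments into one long sequence for interspike-interval
#' testing.
#'
#' @param trains List of [spike_train()]s sharing one window length.
#' @return Numeric vector of merged, ascending spike times.
#' @examples
#' a <- spike_train(c(1, 2), 30); b <- spike_train(0.5, 30)
#' superimpose(list(a, b))   # 1, 2, 30.5
#' @export
superimpose <- function(trains) {
  if (length(trains) == 0L) return(numeric(0))
  Tfs <- vapply(trains, function(s) attr(s, "Tf"), numeric(1))
  if (length(unique(Tfs)) != 1L)
    stop("all spike trains must share the same window length")
  Tf <- Tfs[1]
  out <- unlist(lapply(seq_along(trains), function(i) {
    as.numeric(trains[[i]]) + (i - 1) * Tf
  }))
  sort(out)
}

#' Interspike intervals
#'
#' First differences of an ordered spike sequence.  With fewer than two
#' spikes the sample is empty (with a warning), since no interval is
#' defined.
#'
#' @param times Ordered spike times (a [spike_train()] or plain vector,
#'   e.g. from [superimpose()]).
#' @return Numeric vector of intervals (ms).
#' @examples
#' interspike_intervals(c(1, 3, 6))   # 2, 3
#' @export
interspike_intervals <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L) {
    warning("fewer than 2 spikes: empty ISI sample")
    return(numeric(0))
  }
  diff(times)
}

#' Spike-train CSV round trip
#'
#' Writes/reads a set of trains as a two-column CSV
#' (`trial_id`, `spike_time_ms`).
#'
#' @param trains List of [spike_train()]s.
#' @param path File path.
#' @param Tf Window length (ms) to attach on reading.
#' @return `read_spikes_csv()` returns a list of [spike_train()]s.
#' @export
write_spikes_csv <- function(trains, path) {
  df <- do.call(rbind, lapply(seq_along(trains), function(i) {
    s <- trains[[i]]
    if (length(s) == 0L) return(NULL)
    data.frame(trial_id = i, spike_time_ms = as.numeric(s))
  }))
  if (is.null(df)) df <- data.frame(trial_id = integer(0),
                                    spike_time_ms = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param n_trials Number of trials the file describes (trials with no
#'   spikes are restored as empty trains).
#' @export
read_spikes_csv <- function(path, Tf, n_trials) {
  df <- utils::read.csv(path)
  lapply(seq_len(n_trials), function(i) {
    spike_train(df$spike_time_ms[df$trial_id == i], Tf)
  })
}
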