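# Deterministic synthetic fixtures for tests, demos and self-checks.

#' Baseline synthetic dataset
#'
#' The canonical demo dataset: nominal truth ([fn_params()] defaults),
#' 100 trials of 30 ms at dt = 0.01 ms, stimulus NU = 5, Amax = 100,
#' f0 = 1/3 kHz.  Fully determined by `seed`.
#'
#' @param seed Master seed.
#' @param Nit Optionally override the trial count.
#' @return An [fn_dataset()].
#' @export
make_baseline_dataset <- function(seed, Nit = 100) {
  generate_dataset(fn_params(), fn_scenario(Nit = Nit), seed = seed)
}

#' Synthetic long recording
#'
#' Emulates the shape of a long extracellular recording: a
#' piecewise-constant random stimulus (one level per sampling interval,
#' uniform on `[-amp, amp]`), the model integrated at `truth` on a fine
#' grid, Bernoulli spikes collapsed to a binary indicator at the
#' recording's sampling interval.  Useful for exercising the
#' segmentation / incremental-estimation pipeline without external
#' data; it does not emulate any real neuron's statistics.
#'
#' @param seed Master seed.
#' @param total_ms Total recording length, ms (multiple of
#'   `sampling_ms`).
#' @param sampling_ms Sampling interval, ms.
#' @param truth Generating parameters (default [fn_params()]).
#' @param amp Stimulus amplitude bound (default 100).
#' @param dt Internal integration step, ms (default 0.01; must divide
#'   `sampling_ms`).
#' @return An `fn_recording` (see [fn_recording()]).
#' @export
make_synthetic_long_recording <- function(seed, total_ms, sampling_ms,
                                          truth = fn_params(), amp = 100,
                                          dt = 0.01) {
  n_samp <- total_ms / sampling_ms
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("total_ms must be a multiple of sampling_ms")
  per <- sampling_ms / dt
  if (abs(per - round(per)) > 1e-9)
    stop("sampling_ms must be a multiple of dt")
  n_samp <- round(n_samp); per <- round(per)
  set.seed(seed)
  stim <- stats::runif(n_samp, -amp, amp)
  grid <- time_grid(total_ms, dt)
  rate <- integrate_rate(truth, rep(stim, each = per), grid)
  spikes <- suppressWarnings(sample_spikes_bernoulli(rate))
  indicator <- integer(n_samp)
  indicator[unique(floor(as.numeric(spikes) / sampling_ms)) + 1L] <- 1L
  fn_recording(stim, indicator, sampling_ms)
}

#' Example incremental-estimation series
#'
#' Loads the packaged example series of incremental parameter estimates
#' (sample sizes 25 to 2400) obtained from a long blowfly H1
#' visual-neuron recording, used to demonstrate the relative-error
#' convergence diagnostic on published-scale numbers.
#'
#' @return Data frame with columns `Nit`, `a`, `b`, `c`, `d`, `F`.
#' @examples
#' est <- h1_estimate_series()
#' head(relative_error_series(est))
#' @export
h1_estimate_series <- function() {
  utils::read.csv(system.file("extdata", "h1_incremental_estimates.csv",
                              package = "fnspike"))
}
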