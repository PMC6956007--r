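# Point-process likelihood of spike trains under candidate parameters.
#
# For one trial with rate r(t) and spikes t_1..t_K the log-likelihood is
#   l = -int_0^T r(t) dt + sum_k log r(t_k),
# with the integral taken as the left Riemann sum on the trial grid and
# r(t_k) read at the spike's grid node.  Trials are independent, so the
# joint log-likelihood is the sum over trials.

#' Trial container
#'
#' One stimulus/spike-train pair.  Spike times are mapped to grid nodes
#' at construction: synthetic spikes (emitted at node times) use
#' nearest-node lookup and any time farther than `dt/2` from a node is
#' an error; recorded data (arbitrary times) use `align = "floor"`,
#' assigning each spike to its containing bin.
#'
#' @param stimulus A [stimulus_spec()], or a numeric waveform of length
#'   `grid$n` (e.g. a recorded stimulus segment).
#' @param spikes A [spike_train()].
#' @param grid A [time_grid()].
#' @param align `"nearest"` (synthetic, default) or `"floor"` (recorded).
#' @return An object of class `"fn_trial"` with the stimulus waveform
#'   and 1-based spike node indices precomputed.
#' @export
fn_trial <- function(stimulus, spikes, grid, align = c("nearest", "floor")) {
  align <- match.arg(align)
  stopifnot(inherits(grid, "time_grid"))
  if (inherits(stimulus, "stimulus_spec")) {
    waveform <- evaluate_stimulus(stimulus, grid)
  } else {
    waveform <- as.numeric(stimulus)
    if (length(waveform) != grid$n)
      stop("stimulus waveform length must equal the grid node count")
    stimulus <- NULL
  }
  t <- as.numeric(spikes)
  if (length(t) && (min(t) < 0 || max(t) > grid$Tf))
    stop("spike times outside the trial window")
  if (align == "nearest") {
    idx <- round(t / grid$dt) + 1L
    off <- abs(t - (idx - 1) * grid$dt)
    if (any(off > 1e-6 * grid$dt) || any(idx > grid$n))
      stop("spike time does not align with a grid node")
  } else {
    idx <- pmin(as.integer(floor(t / grid$dt)) + 1L, grid$n)
  }
  structure(list(stimulus = stimulus, waveform = waveform,
                 spikes = spikes, spike_idx = as.integer(idx),
                 grid = grid),
            class = "fn_trial")
}

#' Dataset container
#'
#' A set of independent trials sharing one grid, with the per-trial
#' stimulus waveforms packed into a matrix for fast repeated likelihood
#' evaluation.
#'
#' @param trials List of [fn_trial()]s.
#' @param truth Optional true [fn_params] used to generate the data.
#' @param scenario Optional [fn_scenario()] provenance record.
#' @param seed Optional master seed used for generation.
#' @return An object of class `"fn_dataset"`.
#' @export
fn_dataset <- function(trials, truth = NULL, scenario = NULL, seed = NULL) {
  if (length(trials) < 1L) stop("dataset needs at least one trial")
  grid <- trials[[1]]$grid
  same <- vapply(trials, function(tr)
    isTRUE(all.equal(tr$grid$Tf, grid$Tf)) &&
      isTRUE(all.equal(tr$grid$dt, grid$dt)), logical(1))
  if (!all(same)) stop("all trials must share Tf and dt")
  stim_mat <- vapply(trials, `[[`, numeric(grid$n), "waveform")
  counts <- vapply(trials, function(tr) length(tr$spike_idx), integer(1))
  structure(list(trials = trials, grid = grid,
                 stim_mat = stim_mat,
                 spike_idx = unlist(lapply(trials, `[[`, "spike_idx"),
                                    use.names = FALSE),
                 offsets = cumsum(counts),
                 truth = truth, scenario = scenario, seed = seed),
            class = "fn_dataset")
}

#' @export
print.fn_dataset <- function(x, ...) {
  cat(sprintf("fn_dataset: %d trials of %g ms (dt = %g ms), %d spikes total\n",
              length(x$trials), x$grid$Tf, x$grid$dt, length(x$spike_idx)))
  invisible(x)
}

#' Per-trial point-process log-likelihood
#'
#' @param trial An [fn_trial()].
#' @param rate A `rate_trajectory` computed under the trial's own
#'   stimulus (any candidate parameters).
#' @return Scalar log-likelihood; `-Inf` if the rate underflows to 0 at
#'   a spike node (never `NaN`).
#' @examples
#' g <- time_grid()
#' r <- constant_rate(0.5, g)
#' tr <- fn_trial(rep(0, g$n), spike_train((1:10) * 2, 30), g)
#' trial_log_likelihood(tr, r)   # -0.5*30 + 10*log(0.5)
#' @export
trial_log_likelihood <- function(trial, rate) {
  stopifnot(inherits(trial, "fn_trial"), inherits(rate, "rate_trajectory"))
  if (rate$grid$n != trial$grid$n)
    stop("rate trajectory and trial use different grids")
  r_at_spikes <- rate$rate[trial$spike_idx]
  if (any(r_at_spikes <= 0)) return(-Inf)
  -sum(rate$rate) * rate$grid$dt + sum(log(r_at_spikes))
}

#' Joint log-likelihood over all trials
#'
#' For each trial, re-integrates the model under the trial's stored
#' stimulus waveform at the candidate parameters (initial state (0,0))
#' and accumulates [trial_log_likelihood()] terms in trial order.
#' Integration divergence in any trial yields the `-Inf` sentinel, so
#' bounded optimisers can reject infeasible iterates without an
#' exception.
#'
#' @param dataset An [fn_dataset()].
#' @param params Candidate [fn_params].
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
joint_log_likelihood <- function(dataset, params) {
  stopifnot(inherits(dataset, "fn_dataset"))
  params <- as_fn_params(params)
  nll <- cpp_joint_negll(unclass(params), dataset$stim_mat,
                         dataset$spike_idx, dataset$offsets,
                         dataset$grid$dt, 0, 0,
                         .fn_vclamp, .fn_blowup, .fn_bigval)
  if (nll >= .fn_bigval) return(-Inf)
  -nll
}

# Finite stand-in for +Inf handed to bounded quasi-Newton optimisers,
# which require finite objective values.
.fn_bigval <- 1e15
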