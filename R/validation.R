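# Distributional goodness-of-fit: two-sample Kolmogorov-Smirnov testing
# of interspike-interval samples between a reference set of segments
# and model-simulated spike trains under the same stimuli.

#' Two-sample Kolmogorov-Smirnov test on ISI samples
#'
#' Thin wrapper around the standard two-sample KS routine
#' (`stats::ks.test`) returning the sup-distance of the two empirical
#' CDFs and its asymptotic p-value.  ISI samples from gridded spike
#' times are tie-heavy; the tie warning is suppressed and the
#' asymptotic p-value used throughout.
#'
#' @param sample_a,sample_b Non-empty numeric ISI samples (ms).
#' @return List with `statistic` and `p.value`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(1001, 1002, 1003))$statistic  # 1
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both ISI samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Simulate model spike trains for each segment
#'
#' Replaces every segment's spike train with a fresh model simulation
#' under that segment's own stimulus: the stimulus is resampled to the
#' integration grid by zero-order hold, the model is integrated at
#' `params` from state (0, 0), and spikes are Bernoulli-sampled.  The
#' result is a segment set with the same stimuli but model-generated
#' responses, e.g. the simulated side of a goodness-of-fit comparison,
#' or a reference side drawn from the model's own segment-wise
#' distribution.
#'
#' @param segs An `fn_segments` (see [segment_recording()]).
#' @param params [fn_params] for the simulation.
#' @param dt Integration step, ms.
#' @param stim_scale Stimulus unit conversion.
#' @return An `fn_segments` with simulated spike trains.
#' @export
simulate_segments <- function(segs, params, dt = 0.01, stim_scale = 1) {
  stopifnot(inherits(segs, "fn_segments"))
  params <- as_fn_params(params)
  grid <- time_grid(segs$segment_ms, dt)
  t_nodes <- grid_times(grid)
  segments <- lapply(segs$segments, function(sg) {
    idx <- pmin(floor(t_nodes / segs$sampling_ms) + 1, length(sg$stimulus))
    rate <- integrate_rate(params, stim_scale * sg$stimulus[idx], grid)
    list(stimulus = sg$stimulus,
         spikes = suppressWarnings(sample_spikes_bernoulli(rate)))
  })
  structure(list(segment_ms = segs$segment_ms,
                 sampling_ms = segs$sampling_ms, segments = segments),
            class = "fn_segments")
}

#' KS p-value versus sample count
#'
#' For each requested count `n`, pools (superimposes) the first `n`
#' reference segments' spike trains and the first `n` model-simulated
#' segments' spike trains, takes the interspike intervals of each
#' pooled sequence, and records the two-sample KS p-value.  Model
#' trains are simulated under each segment's own stimulus at
#' `model_params` (integration grid step `dt`, Bernoulli sampling from
#' R's current random stream).
#'
#' @param segs Reference `fn_segments` (recorded or simulated).
#' @param model_params [fn_params] for the simulated side.
#' @param sample_counts Ascending segment counts.
#' @param dt Integration step for the model simulation, ms.
#' @param stim_scale Stimulus unit conversion (see
#'   [segments_to_dataset()]).
#' @return Data frame with columns `n`, `statistic`, `p.value`, plus
#'   attribute `first_accepted`: the smallest `n` with p > 0.05 (NA if
#'   none).
#' @export
pvalue_vs_samples <- function(segs, model_params, sample_counts,
                              dt = 0.01, stim_scale = 1) {
  stopifnot(inherits(segs, "fn_segments"))
  model_params <- as_fn_params(model_params)
  if (is.unsorted(sample_counts, strictly = TRUE))
    stop("sample counts must be strictly ascending")
  n_max <- max(sample_counts)
  if (n_max > length(segs$segments))
    stop("sample count exceeds the number of segments")
  sim <- simulate_segments(
    structure(list(segment_ms = segs$segment_ms,
                   sampling_ms = segs$sampling_ms,
                   segments = segs$segments[seq_len(n_max)]),
              class = "fn_segments"),
    model_params, dt = dt, stim_scale = stim_scale)
  sim_trains <- lapply(sim$segments, `[[`, "spikes")
  ref_trains <- lapply(segs$segments[seq_len(n_max)], `[[`, "spikes")
  out <- data.frame(n = sample_counts, statistic = NA_real_,
                    p.value = NA_real_)
  for (i in seq_along(sample_counts)) {
    n <- sample_counts[i]
    isi_ref <- interspike_intervals(superimpose(ref_trains[seq_len(n)]))
    isi_sim <- interspike_intervals(superimpose(sim_trains[seq_len(n)]))
    kt <- ks_two_sample(isi_ref, isi_sim)
    out$statistic[i] <- kt$statistic
    out$p.value[i] <- kt$p.value
  }
  acc <- out$n[out$p.value > 0.05]
  attr(out, "first_accepted") <- if (length(acc)) acc[1] else NA_integer_
  out
}
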