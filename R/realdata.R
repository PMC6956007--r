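# Long-recording pathway: load a stimulus + spike-indicator recording,
# cut it into fixed-length segments treated as independent trials, and
# estimate on growing subsets of segments.
#
# Recording file dialect: a CSV with columns `stimulus` (numeric) and
# `spike` (0/1 indicator), one row per sampling interval; the sampling
# interval itself is supplied by the caller.  Spike times are the
# indicator positions times the sampling interval.

#' Load a stimulus/spike recording
#'
#' @param path CSV file with numeric column `stimulus` and binary
#'   column `spike` of equal length.
#' @param sampling_ms Sampling interval of the recording, ms.
#' @return An object of class `"fn_recording"`: `stimulus`,
#'   `spike_times` (ms), `sampling_ms`, `duration_ms`.
#' @export
load_recording <- function(path, sampling_ms) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  stopifnot(sampling_ms > 0)
  df <- utils::read.csv(path)
  for (f in c("stimulus", "spike"))
    if (is.null(df[[f]])) stop("recording is missing field '", f, "'")
  if (length(df$stimulus) != length(df$spike))
    stop("field lengths differ between 'stimulus' and 'spike'")
  if (!all(df$spike %in% c(0, 1)))
    stop("field 'spike' must be a binary indicator")
  fn_recording(df$stimulus, df$spike, sampling_ms)
}

#' @rdname load_recording
#' @param stimulus Numeric stimulus vector.
#' @param spike Binary spike-indicator vector (same length).
#' @export
fn_recording <- function(stimulus, spike, sampling_ms) {
  stopifnot(length(stimulus) == length(spike), sampling_ms > 0,
            all(spike %in% c(0, 1)))
  structure(list(stimulus = as.numeric(stimulus),
                 spike_times = (which(spike == 1) - 1) * sampling_ms,
                 sampling_ms = sampling_ms,
                 duration_ms = length(stimulus) * sampling_ms),
            class = "fn_recording")
}

#' Segment a recording into fixed windows
#'
#' Cuts the recording into `floor(duration / segment_ms)` consecutive
#' segments; any trailing remainder is dropped.  Spike times are
#' re-based to segment-local time and the stimulus is sliced
#' identically, so each segment is one (stimulus, spike train) pair.
#'
#' @param rec An `fn_recording`.
#' @param segment_ms Segment length, ms (must not exceed the recording).
#' @return An object of class `"fn_segments"`: list with `segment_ms`,
#'   `sampling_ms` and `segments`, a list of
#'   `list(stimulus = ..., spikes = spike_train)`.
#' @export
segment_recording <- function(rec, segment_ms) {
  stopifnot(inherits(rec, "fn_recording"))
  if (segment_ms <= 0) stop("segment length must be positive")
  if (rec$duration_ms < segment_ms)
    stop("recording shorter than one segment")
  per_seg <- segment_ms / rec$sampling_ms
  if (abs(per_seg - round(per_seg)) > 1e-9)
    stop("segment length must be a multiple of the sampling interval")
  per_seg <- round(per_seg)
  n_seg <- floor(length(rec$stimulus) / per_seg)
  segments <- lapply(seq_len(n_seg), function(s) {
    i0 <- (s - 1) * per_seg
    t0 <- i0 * rec$sampling_ms
    in_seg <- rec$spike_times >= t0 & rec$spike_times < t0 + segment_ms
    list(stimulus = rec$stimulus[(i0 + 1):(i0 + per_seg)],
         spikes = spike_train(rec$spike_times[in_seg] - t0, segment_ms))
  })
  structure(list(segment_ms = segment_ms, sampling_ms = rec$sampling_ms,
                 segments = segments),
            class = "fn_segments")
}

#' @export
print.fn_segments <- function(x, ...) {
  cat(sprintf("segmented recording: %d segments of %g ms (sampled at %g ms)\n",
              length(x$segments), x$segment_ms, x$sampling_ms))
  invisible(x)
}

#' Build an estimation dataset from recording segments
#'
#' Each segment becomes a trial: the recorded stimulus is resampled to
#' the integration grid by zero-order hold and used directly as the
#' model input current (scaled by `stim_scale`), and spikes are
#' assigned to their containing bin.
#'
#' @param segs An `fn_segments`.
#' @param n Use the first `n` segments (default all).
#' @param dt Integration step, ms.
#' @param stim_scale Multiplicative conversion from recorded stimulus
#'   units to model current (default 1).
#' @return An [fn_dataset()].
#' @export
segments_to_dataset <- function(segs, n = length(segs$segments),
                                dt = 0.01, stim_scale = 1) {
  stopifnot(inherits(segs, "fn_segments"), n >= 1,
            n <= length(segs$segments))
  grid <- time_grid(segs$segment_ms, dt)
  t_nodes <- grid_times(grid)
  trials <- lapply(segs$segments[seq_len(n)], function(sg) {
    # zero-order hold: node takes the sample whose interval contains it
    idx <- pmin(floor(t_nodes / segs$sampling_ms) + 1, length(sg$stimulus))
    fn_trial(stim_scale * sg$stimulus[idx], sg$spikes, grid,
             align = "floor")
  })
  fn_dataset(trials)
}

#' Incremental estimation over growing sample subsets
#'
#' For each requested size `n`, estimates the parameters on the first
#' `n` segments and reports the per-size estimates together with the
#' relative-error series between consecutive sizes
#' (see [relative_error_series()]).
#'
#' @param segs An `fn_segments`.
#' @param sample_sizes Ascending segment counts, each within the number
#'   of segments available.
#' @param dt Integration step, ms.
#' @param stim_scale Stimulus unit conversion (see
#'   [segments_to_dataset()]).
#' @param bounds,init,control Passed to [fn_estimate()].
#' @return List with `estimates` (data frame: `Nit` + the five
#'   parameters, `NA` rows for failed sizes), `relative_errors`
#'   (a [relative_error_series()] over the successful sizes) and
#'   `failures`.
#' @export
incremental_estimation <- function(segs, sample_sizes, dt = 0.01,
                                   stim_scale = 1,
                                   bounds = default_bounds(), init = NULL,
                                   control = list()) {
  stopifnot(inherits(segs, "fn_segments"), length(sample_sizes) >= 2)
  if (is.unsorted(sample_sizes, strictly = TRUE))
    stop("sample sizes must be strictly ascending")
  if (max(sample_sizes) > length(segs$segments))
    stop("sample size exceeds the number of segments")
  est <- matrix(NA_real_, length(sample_sizes), 5,
                dimnames = list(NULL, c("a", "b", "c", "d", "F")))
  failures <- character(0)
  for (i in seq_along(sample_sizes)) {
    fit <- tryCatch({
      ds <- segments_to_dataset(segs, sample_sizes[i], dt, stim_scale)
      fn_estimate(ds, bounds = bounds, init = init, control = control)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("n = %d: %s", sample_sizes[i],
                                      conditionMessage(fit)))
    } else {
      est[i, ] <- unclass(fit$theta_hat)
    }
  }
  df <- cbind(data.frame(Nit = sample_sizes), as.data.frame(est))
  ok <- stats::complete.cases(est)
  rel <- if (sum(ok) >= 2) relative_error_series(df[ok, ]) else NULL
  list(estimates = df, relative_errors = rel, failures = failures)
}
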