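# Shared helpers for the fnspike test suite.

nominal_truth <- function() fn_params()  # a=0.08 b=0.056 c=0.064 d=0.333 F=100

# Brute-force two-sample KS statistic: sup over all pooled points of the
# ECDF distance.  Independent of stats::ks.test.
brute_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  Fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(Fx - Fy))
}

# A small synthetic segmented recording at nominal truth, for the
# real-data-pathway and validation tests.  Coarser grid than the
# simulation study to keep the suite fast; the sampling interval equals
# the integration step so the indicator collapse is lossless at the
# nominal (high) firing rate.
small_segments <- function(seed, n_segments = 20, segment_ms = 50,
                           sampling_ms = 0.05, dt = 0.05, amp = 20) {
  rec <- make_synthetic_long_recording(seed,
                                       total_ms = n_segments * segment_ms,
                                       sampling_ms = sampling_ms,
                                       amp = amp, dt = dt)
  segment_recording(rec, segment_ms)
}
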