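# Spike-train simulation: local Bernoulli, thinning, superimposition.

test_that("near-zero rate produces empty trains", {
  g <- time_grid()
  r0 <- structure(list(grid = g, rate = rep(1e-30, g$n)),
                  class = "rate_trajectory")
  set.seed(1)
  expect_length(sample_spikes_bernoulli(r0), 0)
  expect_length(sample_spikes_thinning(r0), 0)
})

test_that("Bernoulli sampler is mean-consistent with the rate integral", {
  g <- time_grid()                       # Tf = 30, dt = 0.01
  r <- constant_rate(0.1, g)             # lambda = 3 per trial
  set.seed(42)
  counts <- replicate(2000, length(sample_spikes_bernoulli(r)))
  expect_lt(abs(mean(counts) - 3), 3 * sqrt(3 / 2000))
  # spike times lie on grid nodes, strictly increasing
  set.seed(43)
  s <- sample_spikes_bernoulli(constant_rate(2, g))
  expect_true(all(abs(s / 0.01 - round(s / 0.01)) < 1e-9))
  expect_true(all(diff(s) > 0))
})

test_that("firing probability is clipped at 1 with a warning", {
  g <- time_grid(Tf = 1, dt = 0.01)
  r <- constant_rate(150, g)             # r * dt = 1.5
  set.seed(2)
  expect_warning(s <- sample_spikes_bernoulli(r), "clipped")
  expect_length(s, g$n)                  # fires in every bin
})

test_that("thinning counts follow the exact Poisson law at constant rate", {
  g <- time_grid()
  r <- constant_rate(0.3, g)             # lambda = 9
  set.seed(7)
  counts <- replicate(5000, length(sample_spikes_thinning(r)))
  lam <- 9
  brk <- c(-0.5, seq(3.5, 14.5), Inf)
  obs <- table(cut(counts, brk))
  p <- diff(c(0, stats::ppois(c(3, 4:14), lam), 1))
  expect_gt(stats::chisq.test(as.vector(obs), p = p)$p.value, 0.01)
})

test_that("Bernoulli and thinning target the same process", {
  set.seed(31)
  g <- time_grid(Tf = 10)
  spec <- stimulus_spec(5, 50, 1/3, sample_phases(5))
  rate <- integrate_rate(fn_params(F = 1), evaluate_stimulus(spec, g), g)
  lam <- sum(rate$rate) * g$dt
  nb <- replicate(3000, length(sample_spikes_bernoulli(rate)))
  nt <- replicate(3000, length(sample_spikes_thinning(rate)))
  se <- sqrt(var(nb) / 3000 + var(nt) / 3000)
  expect_lt(abs(mean(nb) - mean(nt)), 3 * se)
  expect_lt(abs(mean(nb) - lam), 3 * sqrt(lam / 3000))
})

test_that("constant-rate ISIs are exponential", {
  # long windows so complete-interval truncation is negligible
  g <- time_grid(Tf = 1000)
  r <- constant_rate(0.5, g)
  set.seed(77)
  isi <- unlist(replicate(3, interspike_intervals(sample_spikes_bernoulli(r)),
                          simplify = FALSE))
  expect_gt(length(isi), 1000)
  ref <- stats::rexp(length(isi), rate = 0.5)
  expect_gt(suppressWarnings(stats::ks.test(isi, ref))$p.value, 0.01)
})

test_that("superimpose offsets trains by segment index", {
  a <- spike_train(c(1, 2), 30); b <- spike_train(0.5, 30)
  expect_equal(superimpose(list(a, b)), c(1, 2, 30.5))
  expect_equal(superimpose(list(a)), c(1, 2))
  expect_equal(superimpose(list()), numeric(0))
  expect_error(superimpose(list(a, spike_train(1, 10))), "window length")
})

test_that("spike trains validate ordering and round-trip through CSV", {
  expect_error(spike_train(c(2, 1), 30), "strictly increasing")
  expect_error(spike_train(c(1, 31), 30), "strictly increasing")
  trains <- list(spike_train(c(1, 2.5), 30), spike_train(numeric(0), 30),
                 spike_train(29.99, 30))
  f <- tempfile(fileext = ".csv")
  write_spikes_csv(trains, f)
  back <- read_spikes_csv(f, Tf = 30, n_trials = 3)
  expect_equal(lapply(back, as.numeric), lapply(trains, as.numeric))
})

test_that("interspike intervals are first differences", {
  expect_equal(interspike_intervals(c(1, 3, 6)), c(2, 3))
  expect_warning(out <- interspike_intervals(5), "fewer than 2")
  expect_length(out, 0)
})
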