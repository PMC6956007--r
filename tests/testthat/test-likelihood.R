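# Point-process likelihood, per trial and jointly.

test_that("constant-rate likelihood matches the homogeneous closed form", {
  g <- time_grid()
  zero_stim <- rep(0, g$n)
  tr10 <- fn_trial(zero_stim, spike_train((1:10) * 2, 30), g)
  expect_equal(trial_log_likelihood(tr10, constant_rate(0.5, g)),
               -0.5 * 30 + 10 * log(0.5), tolerance = 1e-9)
  tr30 <- fn_trial(zero_stim, spike_train((1:30) * 0.5, 30), g)
  expect_equal(trial_log_likelihood(tr30, constant_rate(1, g)), -30,
               tolerance = 1e-12)
  # zero spikes: exactly minus the Riemann sum
  tr0 <- fn_trial(zero_stim, spike_train(numeric(0), 30), g)
  r <- constant_rate(0.37, g)
  expect_identical(trial_log_likelihood(tr0, r), -sum(r$rate) * 0.01)
  # random constant rates, random spike counts
  set.seed(14)
  for (i in 1:20) {
    rr <- runif(1, 0.05, 3)
    K <- rpois(1, 10) + 1
    tr <- fn_trial(zero_stim, spike_train(sort(sample(0:2999, K)) * 0.01, 30), g)
    expect_equal(trial_log_likelihood(tr, constant_rate(rr, g)),
                 -rr * 30 + K * log(rr), tolerance = 1e-9)
  }
})

test_that("spike times off the grid are rejected for synthetic trials", {
  g <- time_grid()
  expect_error(fn_trial(rep(0, g$n), spike_train(0.013, 30), g),
               "align")
  # floor alignment accepts arbitrary times
  tr <- fn_trial(rep(0, g$n), spike_train(0.013, 30), g, align = "floor")
  expect_equal(tr$spike_idx, 2L)
})

test_that("joint likelihood is additive and permutation-invariant", {
  set.seed(15)
  ds <- generate_dataset(nominal_truth(), fn_scenario(Nit = 6, Tf = 10),
                         seed = 99)
  th <- fn_params(0.1, 0.05, 0.07, 0.3, 90)
  joint <- joint_log_likelihood(ds, th)
  # sum of per-trial R-side evaluations (independent of the C++ path)
  per_trial <- vapply(ds$trials, function(tr) {
    rate <- integrate_rate(th, tr$waveform, tr$grid)
    trial_log_likelihood(tr, rate)
  }, numeric(1))
  expect_equal(joint, sum(per_trial), tolerance = 1e-9)
  # single-trial dataset reduces to the trial term
  expect_equal(joint_log_likelihood(fn_dataset(ds$trials[1]), th),
               per_trial[1], tolerance = 1e-9)
  # permuting trials leaves the value unchanged
  perm <- fn_dataset(ds$trials[c(4, 1, 6, 2, 5, 3)])
  expect_equal(joint_log_likelihood(perm, th), joint, tolerance = 1e-12)
  # M identical trials give M times the single-trial value
  rep_ds <- fn_dataset(ds$trials[rep(2, 5)])
  expect_equal(joint_log_likelihood(rep_ds, th), 5 * per_trial[2],
               tolerance = 1e-9)
})

test_that("infeasible parameters yield the -Inf sentinel, not an error", {
  g <- time_grid(Tf = 5)
  tr <- fn_trial(rep(1e7, g$n), spike_train(numeric(0), 5), g)
  ds <- fn_dataset(list(tr))
  expect_identical(joint_log_likelihood(ds, fn_params(d = 1e-300)), -Inf)
})

test_that("the joint likelihood concentrates near the generating truth", {
  truth <- nominal_truth()
  sc <- fn_scenario(Nit = 50)
  worse <- 0L; total <- 0L; worse_dF <- 0L; total_dF <- 0L
  for (s in 1:10) {
    ds <- generate_dataset(truth, sc, seed = 1000 + s)
    ll_true <- joint_log_likelihood(ds, truth)
    for (j in 1:5) for (f in c(0.5, 1.5)) {
      th <- unclass(truth); th[j] <- th[j] * f
      total <- total + 1L
      drop <- joint_log_likelihood(ds, th) < ll_true
      if (drop) worse <- worse + 1L
      if (j >= 4) { total_dF <- total_dF + 1L
                    if (drop) worse_dF <- worse_dF + 1L }
    }
    # the whole vector scaled +/- 50% is always distinguishable
    expect_lt(joint_log_likelihood(ds, unclass(truth) * 0.5), ll_true)
    expect_lt(joint_log_likelihood(ds, unclass(truth) * 1.5), ll_true)
  }
  # d and F are sharply identified; a, b, c perturbations of this size
  # sit within a few sampling standard deviations, so only require a
  # clear overall majority there
  expect_equal(worse_dF / total_dF, 1)
  expect_gte(worse / total, 0.8)
})
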