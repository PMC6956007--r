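# FitzHugh-Nagumo dynamics, sigmoid rate map, Euler integration.

test_that("fn_derivatives evaluates the vector field exactly", {
  p <- nominal_truth()
  expect_equal(fn_derivatives(c(0, 0), p, I = 0),
               c(dV = 0, dW = 0.08))
  expect_equal(fn_derivatives(c(1, 0), fn_params(a = 0, b = 0, c = 0, d = 0)),
               c(dV = 1, dW = 0))
  # hand evaluation: V=2, W=1, I=0.5
  expect_equal(fn_derivatives(c(2, 1), p, I = 0.5),
               c(dV = 2 - 0.333 * 8 - 1 + 0.5,
                 dW = 0.064 * 2 + 0.08 - 0.056 * 1))
})

test_that("fn_derivatives matches an independent evaluation on random points", {
  set.seed(11)
  for (i in 1:1000) {
    V <- stats::rnorm(1, 0, 3); W <- stats::rnorm(1, 0, 3)
    th <- stats::runif(4); I <- stats::rnorm(1, 0, 100)
    p <- fn_params(th[1], th[2], th[3], th[4], 100)
    got <- fn_derivatives(c(V, W), p, I)
    expect_identical(unname(got[1]), V - th[4] * V^3 - W + I)
    expect_identical(unname(got[2]), th[3] * V + th[1] - th[2] * W)
  }
})

test_that("fn_derivatives rejects non-finite state", {
  expect_error(fn_derivatives(c(NaN, 0), nominal_truth()), "finite")
  expect_error(fn_derivatives(c(0, 0), nominal_truth(), I = Inf), "finite")
})

test_that("firing rate is a scaled sigmoid with strict bounds", {
  expect_equal(firing_rate(0, 100), 50)
  expect_equal(firing_rate(-log(3), 100), 25)
  expect_equal(firing_rate(40, 100), 100, tolerance = 1e-15)
  V <- seq(-30, 30, length.out = 2001)
  r <- firing_rate(V, 100)
  expect_true(all(r > 0 & r < 100))
  expect_true(all(diff(r) >= 0))
  # clamped extremes: still positive below, saturated to F only within
  # floating-point resolution above
  expect_gt(firing_rate(-600, 100), 0)
  expect_lte(firing_rate(600, 100), 100)
  expect_error(firing_rate(0, -1), "positive")
})

test_that("integration from an equilibrium stays flat", {
  # with a = 0, W* = cV*/b; nontrivial V* solves V(1 - c/b) = d V^3
  p <- fn_params(a = 0, b = 0.056, c = 0.02, d = 0.333, F = 100)
  vdot <- function(V) V - 0.333 * V^3 - (0.02 / 0.056) * V
  Vstar <- stats::uniroot(vdot, c(0.5, 5), tol = 1e-14)$root
  Wstar <- 0.02 * Vstar / 0.056
  g <- time_grid(Tf = 10)
  tr <- integrate_rate(p, 0, g, init = c(Vstar, Wstar))
  expect_lt(max(abs(tr$rate - firing_rate(Vstar, 100))), 1e-6 * g$n)
  expect_s3_class(tr, "rate_trajectory")
})

test_that("rate trajectories stay strictly inside (0, F)", {
  set.seed(21)
  g <- time_grid(Tf = 10)
  for (i in 1:10) {
    p <- fn_params(runif(1), runif(1), runif(1), runif(1, 0.05, 1),
                   runif(1, 10, 200))
    spec <- stimulus_spec(5, runif(1, 0, 200), 1/3, sample_phases(5))
    tr <- integrate_rate(p, evaluate_stimulus(spec, g), g)
    expect_true(all(tr$rate > 0 & tr$rate < unclass(p)[5]))
    expect_length(tr$rate, g$n)
  }
})

test_that("Euler integration converges at first order", {
  p <- nominal_truth()
  f0 <- 1/3
  stim_fun <- function(t) 100 * cos(2 * pi * f0 * t)
  Tf <- 5
  ref <- deSolve::ode(
    y = c(V = 0, W = 0), times = c(0, Tf - 0.01),
    func = function(t, y, parms) {
      list(c(y[1] - 0.333 * y[1]^3 - y[2] + stim_fun(t),
             0.064 * y[1] + 0.08 - 0.056 * y[2]))
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  V_ref <- ref[2, "V"]
  final_V <- function(dt) {
    g <- time_grid(Tf, dt)
    tr <- integrate_rate(p, stim_fun(grid_times(g)), g)
    # state at the last node time Tf - 0.01 shared by all grids
    tr$V[g$n - round(0.01 / dt) + 1]
  }
  err <- abs(c(final_V(0.01), final_V(0.001)) - V_ref)
  expect_gt(err[1] / err[2], 5)   # ~10x error reduction for 10x finer step
  expect_lt(err[1] / err[2], 20)
})

test_that("RK4 option tracks the reference solver much closer than Euler", {
  p <- nominal_truth()
  g <- time_grid(5, 0.01)
  stim <- 100 * cos(2 * pi * grid_times(g) / 3)
  ref <- deSolve::ode(
    y = c(V = 0, W = 0), times = c(0, 5 - 0.01),
    func = function(t, y, parms) {
      list(c(y[1] - 0.333 * y[1]^3 - y[2] + 100 * cos(2 * pi * t / 3),
             0.064 * y[1] + 0.08 - 0.056 * y[2]))
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)[2, "V"]
  e_euler <- abs(integrate_rate(p, stim, g)$V[g$n] - ref)
  e_rk4 <- abs(integrate_rate(p, stim, g, method = "rk4")$V[g$n] - ref)
  # RK4 accuracy here is limited by the linear in-step stimulus
  # interpolation, so expect a solid but not 4th-order improvement
  expect_lt(e_rk4, e_euler / 10)
})

test_that("divergent integration fails loudly with the step index", {
  p <- fn_params(d = 0)
  g <- time_grid(Tf = 30)
  expect_error(integrate_rate(p, rep(1e7, g$n), g), "diverged at step")
})

test_that("time grids validate their invariants", {
  g <- time_grid()
  expect_equal(g$n, 3000L)
  expect_equal(grid_times(g)[1:3], c(0, 0.01, 0.02))
  expect_equal(grid_times(g)[g$n], 30 - 0.01)
  expect_error(time_grid(30, 0.007), "integer multiple")
  expect_error(time_grid(-1, 0.01), "positive")
})
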