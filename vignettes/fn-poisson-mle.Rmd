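---
title: "Estimating FitzHugh-Nagumo neuron parameters from spike timings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating FitzHugh-Nagumo neuron parameters from spike timings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In vivo neural recordings rarely deliver a clean membrane-potential
trace; what an extracellular electrode yields is a *spike train* — the
discrete times at which the neuron fired, with no amplitude
information.  `fnspike` asks how much of a mechanistic neuron model can
be recovered from spike timings alone, and answers it for a
firing-rate-modified FitzHugh-Nagumo (FN) neuron driven by a known
stimulus.

## Model

The membrane dynamics are the classical two-variable FN reduction,

$$\dot V = V - d\,V^3 - W + I(t), \qquad \dot W = cV + a - bW,$$

with `V` a membrane-potential-like variable, `W` a lumped recovery
variable and `I(t)` the stimulus current.  The cubic coefficient,
classically fixed at 1/3, is treated as a free parameter `d`.  The
observable is not `V` but an instantaneous firing rate obtained through
a scaled logistic sigmoid,

$$r(t) = \frac{F}{1 + e^{-V(t)}},$$

so `F` is the maximum firing rate (per ms).  The estimation target is
the five-vector $\theta = [a, b, c, d, F]$.  Nominal values used by the
synthetic study are `fn_params()`:
`a = 0.08, b = 0.056, c = 0.064, d = 0.333, F = 100` ms⁻¹.

Spiking is modelled as an inhomogeneous Poisson point process (IPP)
with intensity `r(t)`: spike counts in disjoint windows are independent
Poisson variables with mean $\int r\,dt$.  For a spike train
$t_1 < \dots < t_K$ on $[0, T]$ the point-process log-likelihood is

$$\ell(\theta) = -\int_0^T r(t)\,dt + \sum_{k=1}^K \ln r(t_k),$$

and for $M$ independent trials the joint log-likelihood is the sum of
per-trial terms, each trial's rate re-integrated under its own
stimulus.  The maximum-likelihood estimate is the bounded maximiser of
this sum.

## Stimulus design

Each trial is driven by a phased-cosine Fourier series

$$I(t) = \sum_{n=1}^{NU} A_{\max}\cos(2\pi f_0 n\,t + \phi_n),$$

with common amplitude `Amax`, base frequency `f0` (kHz; with time in ms
the phase argument needs no unit conversion) and phases redrawn
uniformly on $[-\pi, \pi]$ at every trial.  The phases are persisted
with each trial because the likelihood must re-integrate the model
under the *same* stimulus that elicited the spikes.  Randomising only
the phase keeps the stimulus power spectrum fixed across trials while
still exploring the state space.

## Discretisation and numerical choices

Everything lives on one fixed grid: the window $[0, T_f]$ (default
30 ms) is cut into bins of `dt` (default 0.01 ms, i.e. 10 µs), and the
left endpoints `0, dt, ..., Tf - dt` carry the stimulus samples, the
Euler state updates, the spike-generation probabilities and the
likelihood's Riemann sum.  Sharing one discretisation between the
generative model and the fitted likelihood removes a whole class of
alignment errors; the cost is first-order accuracy, which is the
regime the study operates in by design.  A classical RK4 step (with
the stimulus linearly interpolated inside the step) is available via
`integrate_rate(..., method = "rk4")` for cross-checks, but Euler is
the default and the reference path.

Other numerical guards, all chosen once:

* `V` is clamped to ±500 before exponentiation in the sigmoid, so the
  rate never reaches an exact 0 or `F` and `log r` never overflows.
  Within the clamp the map is unchanged to machine precision.
* Integration aborts when `|V|` or `|W|` exceeds 1e6.  Nominal
  trajectories stay O(10), so this unambiguously flags an infeasible
  parameter draw; during optimisation the event is mapped to a huge
  finite objective value (`-Inf` log-likelihood at the user API) so
  the bounded optimiser backs off instead of crashing.
* Initial state is `(V, W) = (0, 0)` for every trial and every
  likelihood evaluation.
* Spike probabilities `r·dt` are clipped at 1 (reachable: with
  `F = 100` ms⁻¹ and `dt = 0.01` ms the product is exactly 1 at
  saturation); the clip triggers a warning because it signals a
  degraded Bernoulli approximation.

## Spike-train simulation

The primary simulator is the local Bernoulli approximation: bin `i`
fires independently with probability `p_i = min(r(t_i)·dt, 1)`, the
spike being stamped at the bin's left-edge node time (no sub-bin
jitter).  An independent thinning sampler — exact IPP simulation by
acceptance of homogeneous Poisson candidates at a dominating rate —
cross-validates it: the two samplers are checked to be mean-consistent
with $\lambda = \int r\,dt$ and distributionally indistinguishable on
count and ISI statistics in the test suite.

## Estimation

`fn_estimate()` maximises the joint log-likelihood with the bounded
quasi-Newton method `L-BFGS-B`, playing the role that an interior-point
solver plays in MATLAB-centric workflows; the acceptance surface is the
estimates, not the iterate path.  Defaults, chosen once:

* Bounds: lower 0 on `a, b, c, d` (all FN parameters are
  non-negative) and 1e-3 on `F` (the rate must stay positive for the
  likelihood to exist); upper `[1, 1, 1, 1, 200]`, enclosing the
  nominal regime with wide margin.  Configurable.
* Initial guess: one uniform draw inside the bounds per estimation run
  (multi-start is deliberately not the default; a single local search
  is the study's operating condition, and the likelihood is observed
  to be well-behaved from random starts at the study's sample sizes).
* Gradients: forward finite differences with relative step 1e-6
  (absolute floor 1e-8), stepping inward at the upper bound.  The
  objective's smoothness is limited by the Euler discretisation, not
  machine epsilon, so a smaller step buys nothing.
* Convergence: `factr = 1e4`, `pgtol = 1e-8`, at most 500 iterations.

## The simulation study

`run_experiment()` repeats (generate dataset at truth → estimate) `R`
times and reports the per-parameter mean and sample standard deviation
(denominator `R - 1`) of the estimates; `sweep_experiments()` tabulates
these across scenario grids in trials `Nit`, component count `NU`,
amplitude `Amax` and base frequency `f0`.  The replication count behind
each summary cell defaults to `R = 50` and is set to `R = 30` in the
package's acceptance checks; all comparisons there use sampling-error
tolerances of the form $3\sigma/\sqrt{R}$, so the conclusions do not
hinge on matching an unstated replication count exactly.  The baseline
scenario is `Nit = 100, NU = 5, Amax = 100, f0 = 1/3 kHz`; the sweep
defaults follow the published grids (`Nit ∈ {25, 50, 100, 200}`,
`NU ∈ {5, 10, 20, 30}`, `Amax ∈ {25, 50, 100, 200}`,
`f0 ∈ {1/3, 1, 5/3, 7/3} kHz`).  The source tables render the
frequency list ambiguously (1/3 vs 10/3 appears in different places);
the sweep accepts an arbitrary `f0` list rather than guessing.

Determinism is end-to-end: one master seed derives per-repetition
seeds, each repetition derives per-trial seeds (stored in the
dataset), and the random initial guess draws from a stream seeded per
repetition, so every cell of every table can be replayed.
Repetitions whose estimation fails are recorded and excluded rather
than silently retried — a retry would bias the dispersion downward.

## Long recordings and incremental estimation

A second pathway mimics fitting to a long recorded session: a
recording (stimulus vector plus binary spike indicator; CSV dialect
with columns `stimulus`, `spike`) is segmented into fixed windows,
each segment treated as an independent trial with its recorded
stimulus resampled to the integration grid by zero-order hold and
applied directly as `I(t)` (unit conversion factor `stim_scale`,
default 1 — the minimal faithful choice, since how a recorded
white-noise stimulus maps to model current units is genuinely
unspecified).  `incremental_estimation()` fits on growing prefixes of
the segment list and summarises convergence with the relative-error
series

$$ER(k) = \frac{|\hat\theta(k) - \hat\theta(k-1)|}{|\hat\theta(k-1)|},$$

taken with absolute values (the published worked examples are
non-negative throughout) and an `Inf` sentinel on division by zero.
`make_synthetic_long_recording()` generates a recording-shaped fixture
(piecewise-constant random stimulus, model at truth, spikes collapsed
to an indicator) so the whole pathway is testable without any external
download.  MATLAB workspace input is not parsed natively; convert to
the CSV dialect first.

## Goodness of fit

`pvalue_vs_samples()` follows the study's distributional validation:
for growing segment counts `n`, the first `n` reference segments and
`n` model-simulated segments (same stimuli, candidate parameters) are
each *superimposed* — concatenated with per-segment time offsets —
ISIs are taken of each pooled sequence, and a two-sample
Kolmogorov-Smirnov test compares them.  Superimposing before ISI
extraction means inter-segment gaps contribute intervals; this mirrors
the validated procedure rather than a statistically purer per-segment
pooling, and is noted as a caveat.  The implementation delegates to
the standard two-sample KS routine with the asymptotic p-value; ISI
samples from gridded spike times are tie-heavy, making the p-values
approximate, which is the same regime the original workflow operated
in.

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions exactly: nominal truth,
30 ms windows, 10 µs bins, phased-cosine stimuli with per-trial random
phases, Bernoulli spiking.  It does **not** emulate refractory
periods, history-dependent (non-Poisson) firing, measurement jitter,
electrode artefacts, or any real neuron's receptive field; a passing
recovery test therefore shows that the estimator inverts its own
generative model at realistic sample sizes, not that the FN model is
the correct description of any particular biological neuron.  The
synthetic long recording likewise has recording *shape*, not blowfly
H1 statistics — published H1-scale estimate magnitudes (with
parameters in the hundreds) are on a different scale from the nominal
truth and are shipped only as a worked example for the relative-error
diagnostic.

## Problem sizes used in the checks

The packaged checks run the baseline recovery at `Nit = 200` and the
low-amplitude cell at `Amax = 25, Nit = 100`, both with `R = 30`
repetitions, and the dispersion-trend sweep across
`Amax ∈ {25, 50, 100, 200}` at `R = 30`; sampler calibrations use 10⁴
replicates and the KS screens pool 40 segments of 50 ms on a 0.05 ms
grid.  These sizes were chosen so each summary statistic carries
enough replication for its $3\sigma/\sqrt{R}$ tolerance to be
meaningful while keeping a full run on a single CPU in the tens of
minutes.

## Known limitations

* Estimates of `a`, `b`, `c` are noticeably noisier than `d` and `F`
  (the study's dispersion tables show the same pattern); single-dataset
  estimates of these coordinates should be read with their standard
  deviations in hand.
* The likelihood is maximised by a local method from one random start;
  pathological starts are rejected via the `-Inf` sentinel but global
  optimality is not guaranteed.
* Analytic gradients through the ODE (sensitivity equations) are not
  implemented; finite differences dominate the runtime.
* The per-bin Bernoulli probability saturates at 1 near `V ≫ 0` at the
  nominal `F`, where the discretised process is locally deterministic;
  the likelihood uses the same discretisation, so this is consistent,
  but it is a visible departure from an ideal continuous-time IPP.
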