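#include <Rcpp.h>
using namespace Rcpp;

// Core numerical kernels for the FitzHugh-Nagumo point-process likelihood.
//
// All grids are left-endpoint grids: n = Tf/dt nodes at times
// 0, dt, ..., Tf - dt.  The rate at node i is the sigmoid of V at node i,
// and sum(r_i) * dt is the left Riemann sum of the rate over [0, Tf].
// The same grid carries the Euler integration, the Bernoulli spike
// sampler and the likelihood, so the generative model and the fitted
// likelihood share one discretisation.

static inline double clampV(double v, double vclamp) {
  if (v > vclamp) return vclamp;
  if (v < -vclamp) return -vclamp;
  return v;
}

// Forward-Euler (or RK4 with zero-order-hold stimulus) integration of
//   Vdot = V - d V^3 - W + I(t)
//   Wdot = c V + a - b W
// Returns V and W at the n grid nodes (state *before* each step, so
// V[0], W[0] are the initial conditions).  diverged_at is the 1-based
// node index where |V| or |W| first exceeded `blowup` (0 if never).
// [[Rcpp::export]]
List cpp_fn_integrate(NumericVector theta, NumericVector stim, double dt,
                      double v0, double w0, double blowup, bool rk4) {
  const double a = theta[0], b = theta[1], c = theta[2], d = theta[3];
  const int n = stim.size();
  NumericVector V(n), W(n);
  double v = v0, w = w0;
  int diverged_at = 0;
  for (int i = 0; i < n; ++i) {
    V[i] = v; W[i] = w;
    if (!R_finite(v) || !R_finite(w) ||
        std::fabs(v) > blowup || std::fabs(w) > blowup) {
      diverged_at = i + 1;
      break;
    }
    const double I = stim[i];
    if (!rk4) {
      const double dv = v - d * v * v * v - w + I;
      const double dw = c * v + a - b * w;
      v += dt * dv;
      w += dt * dw;
    } else {
      // classical RK4; stimulus linearly interpolated within the step
      // (held at the final node's value over the last step)
      const double Iend = (i + 1 < n) ? stim[i + 1] : I;
      const double Imid = 0.5 * (I + Iend);
      double k1v = v - d * v * v * v - w + I;
      double k1w = c * v + a - b * w;
      double v2 = v + 0.5 * dt * k1v, w2 = w + 0.5 * dt * k1w;
      double k2v = v2 - d * v2 * v2 * v2 - w2 + Imid;
      double k2w = c * v2 + a - b * w2;
      double v3 = v + 0.5 * dt * k2v, w3 = w + 0.5 * dt * k2w;
      double k3v = v3 - d * v3 * v3 * v3 - w3 + Imid;
      double k3w = c * v3 + a - b * w3;
      double v4 = v + dt * k3v, w4 = w + dt * k3w;
      double k4v = v4 - d * v4 * v4 * v4 - w4 + Iend;
      double k4w = c * v4 + a - b * w4;
      v += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      w += dt / 6.0 * (k1w + 2.0 * k2w + 2.0 * k3w + k4w);
    }
  }
  return List::create(_["V"] = V, _["W"] = W, _["diverged_at"] = diverged_at);
}

// Joint negative log-likelihood over M trials.
//
// stim is an n x M matrix of per-node stimulus currents.  Spike node
// indices (1-based, on the same grid) for all trials are concatenated in
// spike_idx; trial m owns entries offsets[m-1]+1 .. offsets[m] (offsets
// has length M, cumulative counts).  Returns +Inf is never produced:
// infeasible parameter vectors (integration divergence, rate underflow)
// yield `bigval` so bounded quasi-Newton optimisers can back off.
// [[Rcpp::export]]
double cpp_joint_negll(NumericVector theta, NumericMatrix stim,
                       IntegerVector spike_idx, IntegerVector offsets,
                       double dt, double v0, double w0, double vclamp,
                       double blowup, double bigval) {
  const double a = theta[0], b = theta[1], c = theta[2], d = theta[3],
               F = theta[4];
  const int n = stim.nrow(), M = stim.ncol();
  const double logF = std::log(F);
  double ll = 0.0;
  int sp_lo = 0;
  for (int m = 0; m < M; ++m) {
    const double *I = &stim(0, m);
    const int sp_hi = offsets[m];          // exclusive upper bound, 0-based
    double v = v0, w = w0;
    double sum_sig = 0.0;                  // sum of sigmoid(V_i)
    double sum_logsig = 0.0;               // sum over spikes of log sigmoid
    int sp = sp_lo;
    for (int i = 0; i < n; ++i) {
      if (!R_finite(v) || !R_finite(w) ||
          std::fabs(v) > blowup || std::fabs(w) > blowup)
        return bigval;
      const double vc = clampV(v, vclamp);
      const double e = std::exp(-vc);
      const double sig = 1.0 / (1.0 + e);
      sum_sig += sig;
      while (sp < sp_hi && spike_idx[sp] == i + 1) {
        sum_logsig += std::log(sig);
        ++sp;
      }
      const double dv = v - d * v * v * v - w + I[i];
      const double dw = c * v + a - b * w;
      v += dt * dv;
      w += dt * dw;
    }
    const int K = sp_hi - sp_lo;
    ll += -F * sum_sig * dt + K * logF + sum_logsig;
    sp_lo = sp_hi;
  }
  if (!R_finite(ll)) return bigval;
  return -ll;
}
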