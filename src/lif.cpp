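#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler leaky integrate-and-fire step loop.
//
// Units follow the membrane equation as usually written for this model:
// potentials in mV, currents in nA, resistance in MOhm (so R*I is in mV),
// times in ms inside the loop. Spike handling: at the first suprathreshold
// sample the potential is set to v_spike for exactly one sample (cosmetic
// spike), then clamped at v_reset for the refractory window, after which
// integration resumes from v_reset.

struct LifPars {
  double dt, e_rest, v_thresh, v_spike, v_reset, tau_m, r_m, t_refract;
};

static List lif_loop(const NumericVector& i_syn, const LifPars& p,
                     bool return_trace) {
  const int n = i_syn.size();
  const int refract_steps = (int)std::lround(p.t_refract / p.dt);
  NumericVector v_out = return_trace ? NumericVector(n) : NumericVector(0);
  std::vector<double> spikes_ms;
  double v = p.e_rest;
  int refract_left = 0;
  if (return_trace) v_out[0] = v;
  for (int i = 1; i < n; ++i) {
    double vnew;
    if (refract_left > 0) {
      vnew = p.v_reset;
      --refract_left;
    } else {
      vnew = v + (p.dt / p.tau_m) * (-(v - p.e_rest) + p.r_m * i_syn[i - 1]);
      if (vnew >= p.v_thresh) {
        spikes_ms.push_back(i * p.dt);
        if (return_trace) v_out[i] = p.v_spike;
        refract_left = refract_steps;
        v = p.v_reset;  // value integration resumes from after refractoriness
        // the visible sample is v_spike; continue with next i
        if (return_trace) continue;
        continue;
      }
    }
    v = vnew;
    if (return_trace) v_out[i] = v;
  }
  NumericVector st(spikes_ms.begin(), spikes_ms.end());
  st = st / 1000.0;  // back to seconds
  List out = List::create(_["spike_times"] = st,
                          _["n_spikes"] = (int)spikes_ms.size());
  if (return_trace) out["v"] = v_out;
  return out;
}

// [[Rcpp::export]]
List lif_integrate_cpp(NumericVector i_syn, double dt, double e_rest,
                       double v_thresh, double v_spike, double v_reset,
                       double tau_m, double r_m, double t_refract,
                       bool return_trace = true) {
  LifPars p{dt, e_rest, v_thresh, v_spike, v_reset, tau_m, r_m, t_refract};
  return lif_loop(i_syn, p, return_trace);
}

// Exponential EPSC superposition sampled on the dt grid, by linear recursion:
// I[k] = I[k-1] * exp(-dt/tau) + i0 * (#spikes landing at sample k).
// A spike contributes its full amplitude i0 at the first grid sample at or
// after its own time (inclusive onset).
// [[Rcpp::export]]
NumericVector epsc_current_cpp(NumericVector spike_times_s, double duration_s,
                               double dt_ms, double i0_na, double tau_epsc_ms) {
  const int n = (int)std::lround(duration_s * 1000.0 / dt_ms) + 1;
  NumericVector cur(n);
  for (int k = 0; k < spike_times_s.size(); ++k) {
    double t_ms = spike_times_s[k] * 1000.0;
    int idx = (int)std::ceil(t_ms / dt_ms - 1e-9);
    if (idx < 0) idx = 0;
    if (idx < n) cur[idx] += i0_na;
  }
  const double decay = std::exp(-dt_ms / tau_epsc_ms);
  for (int i = 1; i < n; ++i) cur[i] += cur[i - 1] * decay;
  return cur;
}

// Fused path used by the simulation sweeps: EPSC recursion and Euler loop in
// one pass, never materialising the current trace in R.
// [[Rcpp::export]]
List lif_from_spikes_cpp(NumericVector spike_times_s, double duration_s,
                         double dt, double e_rest, double v_thresh,
                         double v_spike, double v_reset, double tau_m,
                         double r_m, double t_refract, double i0,
                         double tau_epsc, bool return_trace = false) {
  NumericVector cur =
      epsc_current_cpp(spike_times_s, duration_s, dt, i0, tau_epsc);
  LifPars p{dt, e_rest, v_thresh, v_spike, v_reset, tau_m, r_m, t_refract};
  List out = lif_loop(cur, p, return_trace);
  if (return_trace) out["i_syn"] = cur;
  return out;
}
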