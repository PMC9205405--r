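#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Current-based leaky integrate-and-fire network with exponential synapses.
//
// Each synaptic state s_j decays with time constant tau_s[j] and jumps by a
// weight when a presynaptic event arrives.  Each neuron integrates
//   dV/dt = -V/tau_m + sum(states targeting it) + tonic_drive.
// Between grid points the state and membrane equations are propagated with
// their closed-form solution (events and threshold checks are quantised to
// the dt grid; the dynamics in between are exact).  On crossing the
// threshold the neuron spikes, V <- reset, and integration is suspended for
// the neuron refractory period; outgoing internal connections deliver their
// weight to the target state immediately.
//
// External input spikes are (time, source) pairs sorted by time; each source
// fans out to the states listed in its CSR slice of (map_state, map_weight).
// All times and time constants are in seconds.
//
// [[Rcpp::export]]
List lif_simulate_cpp(NumericVector tau_m, NumericVector threshold,
                      NumericVector reset, NumericVector refractory,
                      NumericVector tonic,
                      NumericVector tau_s, IntegerVector state_post,
                      NumericVector ev_time, IntegerVector ev_src,
                      IntegerVector src_ptr, IntegerVector map_state,
                      NumericVector map_weight,
                      IntegerVector conn_src, IntegerVector conn_state,
                      NumericVector conn_weight,
                      double dt, double span,
                      IntegerVector record_v) {
  const int n_neu = tau_m.size();
  const int n_st = tau_s.size();
  const R_xlen_t n_ev = ev_time.size();
  const int n_steps = static_cast<int>(std::ceil(span / dt - 1e-9));

  // per-state decay and exact membrane coupling over one step
  std::vector<double> dec_s(n_st), coef(n_st);
  for (int j = 0; j < n_st; ++j) {
    const int p = state_post[j];
    if (p < 0 || p >= n_neu) stop("state post index out of range");
    const double tm = tau_m[p], ts = tau_s[j];
    dec_s[j] = std::exp(-dt / ts);
    if (std::fabs(1.0 / tm - 1.0 / ts) < 1e-9) {
      coef[j] = dt * std::exp(-dt / tm);
    } else {
      coef[j] = (std::exp(-dt / ts) - std::exp(-dt / tm)) /
                (1.0 / tm - 1.0 / ts);
    }
  }
  std::vector<double> dec_m(n_neu), ton_c(n_neu);
  for (int i = 0; i < n_neu; ++i) {
    dec_m[i] = std::exp(-dt / tau_m[i]);
    ton_c[i] = tonic[i] * tau_m[i] * (1.0 - dec_m[i]);
  }

  // adjacency for internal connections, grouped by source neuron
  std::vector<std::vector<std::pair<int, double> > > out(n_neu);
  for (R_xlen_t c = 0; c < conn_src.size(); ++c) {
    if (conn_src[c] < 0 || conn_src[c] >= n_neu) stop("bad connection source");
    if (conn_state[c] < 0 || conn_state[c] >= n_st) stop("bad connection state");
    out[conn_src[c]].push_back(std::make_pair(conn_state[c], conn_weight[c]));
  }

  std::vector<double> S(n_st, 0.0), V(n_neu, 0.0), acc(n_neu);
  std::vector<double> refr_until(n_neu, R_NegInf);
  std::vector<int> spike_neuron;
  std::vector<double> spike_time;

  const int n_rec = record_v.size();
  NumericMatrix vtrace(n_rec > 0 ? n_steps + 1 : 0, n_rec);

  R_xlen_t ev = 0;
  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    const double t1 = t + dt;
    // deliver external events due at or before this grid point
    while (ev < n_ev && ev_time[ev] <= t + 1e-12) {
      const int s = ev_src[ev];
      for (int q = src_ptr[s]; q < src_ptr[s + 1]; ++q)
        S[map_state[q]] += map_weight[q];
      ++ev;
    }
    if (n_rec > 0 && k == 0)
      for (int q = 0; q < n_rec; ++q) vtrace(0, q) = V[record_v[q]];
    // membrane update: exact propagation over [t, t1]
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < n_st; ++j) acc[state_post[j]] += S[j] * coef[j];
    for (int i = 0; i < n_neu; ++i) {
      if (t < refr_until[i] - 1e-12) {
        V[i] = reset[i];
      } else {
        V[i] = V[i] * dec_m[i] + acc[i] + ton_c[i];
        if (!R_finite(V[i]))
          stop("non-finite membrane state in neuron %d near t = %g s",
               i + 1, t1);
      }
    }
    for (int j = 0; j < n_st; ++j) S[j] *= dec_s[j];
    // threshold crossings at the end of the step
    for (int i = 0; i < n_neu; ++i) {
      if (t < refr_until[i] - 1e-12) continue;
      if (V[i] > threshold[i]) {
        spike_neuron.push_back(i + 1);
        spike_time.push_back(t1);
        V[i] = reset[i];
        refr_until[i] = t1 + refractory[i];
        const std::vector<std::pair<int, double> > &oc = out[i];
        for (size_t c = 0; c < oc.size(); ++c) S[oc[c].first] += oc[c].second;
      }
    }
    if (n_rec > 0)
      for (int q = 0; q < n_rec; ++q) vtrace(k + 1, q) = V[record_v[q]];
  }

  return List::create(_["neuron"] = wrap(spike_neuron),
                      _["time"] = wrap(spike_time),
                      _["v"] = vtrace,
                      _["n_steps"] = n_steps);
}
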