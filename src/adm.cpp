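#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous delta modulation of a sampled signal.
//
// Classic tracking modulator: a running reference r starts at x[0]; when the
// signal rises more than delta above r an UP spike is emitted and r <- r +
// delta, when it falls more than delta below r a DN spike is emitted and
// r <- r - delta.  A spike of either polarity blocks both polarities for
// `refractory` seconds (single-circuit modulator).  At most one spike is
// emitted per sample, so spike times are strictly increasing.
//
// [[Rcpp::export]]
List adm_encode_cpp(NumericVector x, double fs, double delta,
                    double refractory) {
  const R_xlen_t n = x.size();
  if (n < 1) stop("empty signal");
  if (!(delta > 0)) stop("delta must be > 0 (degenerate modulator)");
  std::vector<double> times;
  std::vector<int> pol;
  double r = x[0];
  double last = R_NegInf;
  // tolerate float fuzz so an inter-sample gap equal to the refractory passes
  const double rmin = refractory * (1.0 - 1e-9);
  for (R_xlen_t i = 1; i < n; ++i) {
    const double t = static_cast<double>(i) / fs;
    if (t - last < rmin) continue;
    const double d = x[i] - r;
    if (d > delta) {
      times.push_back(t);
      pol.push_back(1);
      r += delta;
      last = t;
    } else if (-d > delta) {
      times.push_back(t);
      pol.push_back(-1);
      r -= delta;
      last = t;
    }
  }
  return List::create(_["time"] = wrap(times), _["polarity"] = wrap(pol));
}
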