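#include <Rcpp.h>
using namespace Rcpp;

// Three-store transmitter-depletion synapse (free pool q, cleft c,
// reprocessing store w), forward-Euler at the model rate. The permeability
// k(t) saturates with the driving signal, giving compressive rate-level
// growth; pool depletion gives onset emphasis and adaptation. Output is the
// instantaneous firing rate h * c in spikes/s. States start at their
// steady-state values for s = 0 so silence yields the spontaneous rate from
// the first sample.
// [[Rcpp::export]]
NumericVector meddis_synapse(NumericVector s, double dt,
                             double A, double B, double g, double y,
                             double l, double r, double x, double M,
                             double h) {
  int n = s.size();
  NumericVector out(n);
  double k0 = g * A / (A + B);
  double q = y * M / (y + k0 * l / (l + r));
  double c = k0 * q / (l + r);
  double w = r * c / x;
  for (int i = 0; i < n; ++i) {
    double st = s[i];
    double k = (st + A > 0) ? g * (st + A) / (st + A + B) : 0.0;
    double dq = (y * (M - q) + x * w - k * q) * dt;
    double dc = (k * q - (l + r) * c) * dt;
    double dw = (r * c - x * w) * dt;
    q += dq; c += dc; w += dw;
    if (q < 0) q = 0;
    if (c < 0) c = 0;
    if (w < 0) w = 0;
    out[i] = h * c;
  }
  return out;
}
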