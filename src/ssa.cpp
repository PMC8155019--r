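#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation of a reaction network with linear
// propensities w = W1 * x + w0.  States are sampled onto `sample_times`
// (sorted, inside [t0, t_end]).  Optionally records the full event log so
// per-polymerase bookkeeping (escape/completion times for ChIP mapping)
// can be reconstructed in R.  Uses R's RNG: set.seed() upstream gives
// bit-for-bit reproducibility.
// [[Rcpp::export]]
List ssa_core(const NumericMatrix& S, const NumericMatrix& W1,
              const NumericVector& w0, const NumericVector& x0,
              double t0, double t_end, const NumericVector& sample_times,
              bool record_events, double max_count) {
  const int n_sp = S.nrow(), n_rx = S.ncol(), n_samp = sample_times.size();
  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix states(n_samp, n_sp);
  std::vector<double> ev_t;
  std::vector<int> ev_r;
  if (record_events) { ev_t.reserve(1 << 16); ev_r.reserve(1 << 16); }

  double t = t0;
  int is = 0;
  std::vector<double> a(n_rx);
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < n_rx; ++j) {
      double aj = w0[j];
      for (int i = 0; i < n_sp; ++i) aj += W1(j, i) * x[i];
      if (aj < 0.0) aj = 0.0;
      a[j] = aj;
      a0 += aj;
    }
    double t_next = (a0 > 0.0) ? t + R::exp_rand() / a0 : R_PosInf;
    // flush samples falling before the next event
    while (is < n_samp && sample_times[is] < t_next) {
      for (int i = 0; i < n_sp; ++i) states(is, i) = x[i];
      ++is;
    }
    if (t_next > t_end) break;
    t = t_next;
    double u = unif_rand() * a0, c = 0.0;
    int j = n_rx - 1;
    for (int k = 0; k < n_rx; ++k) {
      c += a[k];
      if (u <= c) { j = k; break; }
    }
    double tot = 0.0;
    for (int i = 0; i < n_sp; ++i) {
      x[i] += S(i, j);
      if (x[i] < 0.0) x[i] = 0.0;  // guard against FP round-off only
      tot += x[i];
    }
    if (tot > max_count)
      stop("state count exceeded %g at t = %g: unstable model", max_count, t);
    if (record_events) { ev_t.push_back(t); ev_r.push_back(j + 1); }
  }
  List out = List::create(_["states"] = states);
  if (record_events) {
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_reaction"] = IntegerVector(ev_r.begin(), ev_r.end());
  }
  return out;
}
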