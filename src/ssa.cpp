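// Exact stochastic simulation (Gillespie direct method) for extended
// stochastic Petri nets: standard / inhibitor / read / equal input arcs,
// optional place capacities, constant-hazard or mass-action propensities.
// Uses R's RNG so seeds set from R give reproducible event sequences.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int KIND_STD = 0, KIND_INH = 1, KIND_READ = 2, KIND_EQ = 3;

// binomial coefficient choose(m, w) for small w; 0 when m < w
static double small_choose(int m, int w) {
  if (m < w) return 0.0;
  double r = 1.0;
  for (int i = 0; i < w; ++i) r *= (double)(m - i) / (double)(w - i);
  return r;
}

struct NetC {
  int nP, nT;
  const int *pre_ptr, *pre_place, *pre_w, *pre_kind;
  const int *d_ptr, *d_place, *d_delta;
  const int *cap; // -1 for unbounded
  const double *rates;
  int semantics;  // 0 constant hazard, 1 mass action

  bool enabled(const std::vector<int> &m, int t) const {
    for (int k = pre_ptr[t]; k < pre_ptr[t + 1]; ++k) {
      int tok = m[pre_place[k]], w = pre_w[k];
      switch (pre_kind[k]) {
      case KIND_STD:
      case KIND_READ: if (tok < w) return false; break;
      case KIND_INH:  if (tok >= w) return false; break;
      case KIND_EQ:   if (tok != w) return false; break;
      }
    }
    for (int k = d_ptr[t]; k < d_ptr[t + 1]; ++k) {
      int p = d_place[k];
      if (cap[p] >= 0 && m[p] + d_delta[k] > cap[p]) return false;
    }
    return true;
  }

  double propensity(const std::vector<int> &m, int t) const {
    if (!enabled(m, t)) return 0.0;
    double a = rates[t];
    if (a <= 0.0) return 0.0;
    if (semantics == 1) {
      for (int k = pre_ptr[t]; k < pre_ptr[t + 1]; ++k)
        if (pre_kind[k] == KIND_STD)
          a *= small_choose(m[pre_place[k]], pre_w[k]);
    }
    return a;
  }

  void apply(std::vector<int> &m, int t) const {
    for (int k = d_ptr[t]; k < d_ptr[t + 1]; ++k) m[d_place[k]] += d_delta[k];
  }
};

// [[Rcpp::export]]
List ssa_run_cpp(int nP,
                 IntegerVector pre_ptr, IntegerVector pre_place,
                 IntegerVector pre_w, IntegerVector pre_kind,
                 IntegerVector d_ptr, IntegerVector d_place,
                 IntegerVector d_delta,
                 IntegerVector cap,
                 IntegerVector m0, NumericVector rates,
                 double t_end, int semantics,
                 bool record_events, NumericVector grid,
                 double max_events) {
  NetC net;
  net.nP = nP; net.nT = rates.size();
  net.pre_ptr = pre_ptr.begin(); net.pre_place = pre_place.begin();
  net.pre_w = pre_w.begin(); net.pre_kind = pre_kind.begin();
  net.d_ptr = d_ptr.begin(); net.d_place = d_place.begin();
  net.d_delta = d_delta.begin();
  net.cap = cap.begin(); net.rates = rates.begin();
  net.semantics = semantics;

  std::vector<int> m(m0.begin(), m0.end());
  std::vector<double> a(net.nT);

  int nG = grid.size(), gi = 0;
  IntegerMatrix grid_states(nG > 0 ? nP : 0, nG);
  std::vector<double> ev_times;
  std::vector<int> ev_fired;
  std::vector<int> ev_states;
  if (record_events) {
    ev_times.push_back(0.0);
    ev_fired.push_back(NA_INTEGER);
    ev_states.insert(ev_states.end(), m.begin(), m.end());
  }

  double t = 0.0, n_events = 0.0;
  bool deadlock = false;
  double deadlock_time = NA_REAL;

  RNGScope scope;
  for (;;) {
    double A = 0.0;
    for (int j = 0; j < net.nT; ++j) { a[j] = net.propensity(m, j); A += a[j]; }
    if (A <= 0.0) {
      deadlock = true; deadlock_time = t;
      break;
    }
    double tau = exp_rand() / A;
    double tnew = t + tau;
    if (tnew >= t_end) break;
    double u = unif_rand() * A, cum = 0.0;
    int j = net.nT - 1;
    for (int jj = 0; jj < net.nT; ++jj) {
      cum += a[jj];
      if (u <= cum) { j = jj; break; }
    }
    // marking is right-continuous: grid points before the event keep m
    while (gi < nG && grid[gi] < tnew) {
      for (int p = 0; p < nP; ++p) grid_states(p, gi) = m[p];
      ++gi;
    }
    net.apply(m, j);
    t = tnew;
    if (record_events) {
      ev_times.push_back(t);
      ev_fired.push_back(j + 1);
      ev_states.insert(ev_states.end(), m.begin(), m.end());
    }
    if (++n_events > max_events)
      stop("ssa: event count exceeded max_events (%.0f)", max_events);
  }
  while (gi < nG) {
    for (int p = 0; p < nP; ++p) grid_states(p, gi) = m[p];
    ++gi;
  }

  List out = List::create(
    _["deadlock"] = deadlock,
    _["deadlock_time"] = deadlock_time,
    _["n_events"] = n_events,
    _["final_marking"] = IntegerVector(m.begin(), m.end()));
  if (nG > 0) out["grid_states"] = grid_states;
  if (record_events) {
    int ne = ev_times.size();
    IntegerMatrix st(nP, ne);
    for (int e = 0; e < ne; ++e)
      for (int p = 0; p < nP; ++p) st(p, e) = ev_states[(size_t)e * nP + p];
    out["times"] = NumericVector(ev_times.begin(), ev_times.end());
    out["fired"] = IntegerVector(ev_fired.begin(), ev_fired.end());
    out["states"] = st;
  }
  return out;
}
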