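#include <Rcpp.h>
using namespace Rcpp;

// Model codes shared with the R side (see R/models.R):
//   0 TM, 1 TSM, 2 CPM, 3 PFM, 4 NFM
// Parameter vector layout (8 slots, unused slots zero):
//   [0] lam (or lam1), [1] lam2, [2] q1, [3] gam, [4] rho, [5] mu, [6] nu, [7] d
// Gene-state coding: the active (on) state is always the highest index
// (1 for TM/PFM/NFM, 2 for TSM/CPM); inactive states are below it.

static inline double fcoop(int n, int coop, int form) {
  if (coop == 1) return (double) n;
  if (form == 0) return (double) n * (double) (n - 1); // mass action n(n-1)
  return (double) n * (double) n;                      // Hill-like n^2
}

struct Props {
  double a_syn, a_dec, a_sw;
};

static inline void propensities(int model, const double* p, int coop, int form,
                                int g, int n, double rho, Props& a) {
  const double lam1 = p[0], lam2 = p[1], gam = p[3], mu = p[5], nu = p[6], d = p[7];
  int on = (model == 1 || model == 2) ? 2 : 1;
  a.a_syn = (g == on) ? rho : 0.0;
  a.a_dec = d * n;
  switch (model) {
  case 0: // TM
    a.a_sw = (g == 0) ? lam1 : gam; break;
  case 1: // TSM: off1 -> off2 -> on -> off1
    a.a_sw = (g == 0) ? lam1 : (g == 1 ? lam2 : gam); break;
  case 2: // CPM: offw -> on (lam1), offs -> on (lam2), on -> offw/offs (gam)
    a.a_sw = (g == 0) ? lam1 : (g == 1 ? lam2 : gam); break;
  case 3: // PFM
    a.a_sw = (g == 0) ? lam1 + mu * fcoop(n, coop, form) : gam; break;
  default: // NFM
    a.a_sw = (g == 0) ? lam1 : gam + nu * fcoop(n, coop, form); break;
  }
}

// advance (g, n) to time t_end; returns by reference
static inline void ssa_advance(int model, const double* p, int coop, int form,
                               double rho, double t_end, int& g, int& n) {
  const double q1 = p[2];
  int on = (model == 1 || model == 2) ? 2 : 1;
  double t = 0.0;
  Props a;
  for (;;) {
    propensities(model, p, coop, form, g, n, rho, a);
    double a0 = a.a_syn + a.a_dec + a.a_sw;
    if (a0 <= 0.0) return; // absorbing state
    t += -std::log(unif_rand()) / a0;
    if (t >= t_end) return;
    double u = unif_rand() * a0;
    if (u < a.a_syn) {
      ++n;
    } else if (u < a.a_syn + a.a_dec) {
      --n;
    } else { // switching
      if (g == on) {
        if (model == 2) g = (unif_rand() < q1) ? 0 : 1; // CPM branching
        else g = 0;
      } else if (model == 1) { // TSM chain off1 -> off2 -> on
        g = (g == 0) ? 1 : 2;
      } else if (model == 2) { // CPM: either off state activates
        g = 2;
      } else {
        g = 1;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_ssa_steady(int model, NumericVector pars, int coop, int form,
                             int n_cells, double burn_in, NumericVector rho_cell,
                             IntegerVector init_state) {
  IntegerMatrix out(n_cells, 2);
  const double* p = pars.begin();
  bool per_cell = rho_cell.size() == n_cells;
  bool per_init = init_state.size() == n_cells;
  for (int c = 0; c < n_cells; ++c) {
    int g = per_init ? init_state[c] : 0, n = 0;
    double rho = per_cell ? rho_cell[c] : p[4];
    ssa_advance(model, p, coop, form, rho, burn_in, g, n);
    out(c, 0) = n;
    out(c, 1) = g;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ssa_snapshots(int model, NumericVector pars, int coop, int form,
                       int n_cells, NumericVector times, IntegerVector init_state,
                       NumericVector rho_cell) {
  int nt = times.size();
  IntegerMatrix counts(n_cells, nt), states(n_cells, nt);
  const double* p = pars.begin();
  bool per_cell = rho_cell.size() == n_cells;
  for (int c = 0; c < n_cells; ++c) {
    int g = init_state.size() == n_cells ? init_state[c] : init_state[0];
    int n = 0;
    double rho = per_cell ? rho_cell[c] : p[4];
    double t_prev = 0.0;
    for (int l = 0; l < nt; ++l) {
      ssa_advance(model, p, coop, form, rho, times[l] - t_prev, g, n);
      t_prev = times[l];
      counts(c, l) = n;
      states(c, l) = g;
    }
  }
  return List::create(_["counts"] = counts, _["states"] = states);
}

// Time-averaged occupancy of (gene state, count) along one trajectory:
// ergodic estimator of the stationary joint distribution. Counts above
// nmax are pooled into the top bin (callers size nmax generously).
// [[Rcpp::export]]
NumericMatrix cpp_ssa_occupancy(int model, NumericVector pars, int coop,
                                int form, double t_burn, double t_total,
                                int nmax) {
  const double* p = pars.begin();
  const double q1 = p[2];
  int S = (model == 1 || model == 2) ? 3 : 2;
  int on = S - 1;
  NumericMatrix occ(S, nmax + 1);
  int g = 0, n = 0;
  double t = 0.0, t_end = t_burn + t_total;
  Props a;
  for (;;) {
    propensities(model, p, coop, form, g, n, p[4], a);
    double a0 = a.a_syn + a.a_dec + a.a_sw;
    double t_next;
    if (a0 <= 0.0) t_next = t_end;
    else t_next = t + -std::log(unif_rand()) / a0;
    if (t_next > t_end) t_next = t_end;
    double lo = t > t_burn ? t : t_burn;
    if (t_next > lo) occ(g, n > nmax ? nmax : n) += t_next - lo;
    if (t_next >= t_end) break;
    t = t_next;
    double u = unif_rand() * a0;
    if (u < a.a_syn) ++n;
    else if (u < a.a_syn + a.a_dec) --n;
    else {
      if (g == on) g = (model == 2) ? (unif_rand() < q1 ? 0 : 1) : 0;
      else if (model == 1) g = (g == 0) ? 1 : 2;
      else if (model == 2) g = 2;
      else g = 1;
    }
  }
  return occ;
}

// [[Rcpp::export]]
List cpp_ssa_trajectory(int model, NumericVector pars, int coop, int form,
                        double t_end, int g0, int n0, int max_events) {
  const double* p = pars.begin();
  const double q1 = p[2];
  int on = (model == 1 || model == 2) ? 2 : 1;
  std::vector<double> times;
  std::vector<int> gs, ns;
  times.reserve(1024); gs.reserve(1024); ns.reserve(1024);
  int g = g0, n = n0;
  double t = 0.0;
  times.push_back(0.0); gs.push_back(g); ns.push_back(n);
  Props a;
  for (int ev = 0; ev < max_events; ++ev) {
    propensities(model, p, coop, form, g, n, p[4], a);
    double a0 = a.a_syn + a.a_dec + a.a_sw;
    if (a0 <= 0.0) break;
    t += -std::log(unif_rand()) / a0;
    if (t >= t_end) break;
    double u = unif_rand() * a0;
    if (u < a.a_syn) ++n;
    else if (u < a.a_syn + a.a_dec) --n;
    else {
      if (g == on) g = (model == 2) ? (unif_rand() < q1 ? 0 : 1) : 0;
      else if (model == 1) g = (g == 0) ? 1 : 2;
      else if (model == 2) g = 2;
      else g = 1;
    }
    times.push_back(t); gs.push_back(g); ns.push_back(n);
  }
  return List::create(_["time"] = wrap(times), _["gene_state"] = wrap(gs),
                      _["count"] = wrap(ns), _["t_end"] = t_end);
}
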