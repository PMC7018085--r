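#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

// mt19937 is bit-reproducible across platforms; the distributions in
// <random> are not, so uniform/normal draws are derived by hand.
struct RngMT {
  std::mt19937 gen;
  bool has_spare = false;
  double spare = 0.0;
  explicit RngMT(unsigned int seed) : gen(seed) {}
  double unif() {                       // [0, 1)
    return gen() * (1.0 / 4294967296.0);
  }
  double gauss() {                      // Box-Muller, cached pair
    if (has_spare) { has_spare = false; return spare; }
    double u1 = 0.0, u2;
    while (u1 <= 0.0) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// Damped synchronous tanh fixed-point iteration with clamped stimulus
// nodes; x is updated in place. Returns iterations used (negative if the
// tolerance was not reached).
static int propagate_core(std::vector<double> &x,
                          const std::vector<int> &src,
                          const std::vector<int> &dst,
                          const std::vector<double> &w,
                          const std::vector<int> &clamp_idx,
                          const std::vector<double> &clamp_val,
                          int max_iter, double tol, double damping) {
  const int n = (int)x.size();
  const int m = (int)src.size();
  std::vector<char> clamped(n, 0);
  for (size_t k = 0; k < clamp_idx.size(); ++k) {
    clamped[clamp_idx[k]] = 1;
    x[clamp_idx[k]] = clamp_val[k];
  }
  std::vector<double> inp(n);
  for (int it = 1; it <= max_iter; ++it) {
    std::fill(inp.begin(), inp.end(), 0.0);
    for (int l = 0; l < m; ++l) inp[dst[l]] += w[l] * x[src[l]];
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      if (clamped[i]) continue;
      double xn = (1.0 - damping) * std::tanh(inp[i]) + damping * x[i];
      double d = std::fabs(xn - x[i]);
      if (d > delta) delta = d;
      x[i] = xn;
    }
    if (delta < tol) return it;
  }
  return -max_iter;
}

// [[Rcpp::export]]
NumericVector cpp_propagate(int n, IntegerVector src, IntegerVector dst,
                            NumericVector w, IntegerVector clamp_idx,
                            NumericVector clamp_val, int max_iter,
                            double tol, double damping) {
  std::vector<double> x(n, 0.0);
  std::vector<int> s(src.begin(), src.end()), d(dst.begin(), dst.end());
  std::vector<double> ww(w.begin(), w.end());
  std::vector<int> ci(clamp_idx.begin(), clamp_idx.end());
  std::vector<double> cv(clamp_val.begin(), clamp_val.end());
  int it = propagate_core(x, s, d, ww, ci, cv, max_iter, tol, damping);
  NumericVector out(x.begin(), x.end());
  out.attr("iterations") = std::abs(it);
  out.attr("converged") = (it > 0);
  return out;
}

// Objective: number of satisfied restrictions, with a continuous tie-break
// on the restriction-aligned signal (scaled to stay below one restriction
// unit so the ordering is lexicographic).
static double objective(const std::vector<double> &x,
                        const std::vector<int> &ridx,
                        const std::vector<double> &rstate,
                        double min_mag, int *nsat_out) {
  int nsat = 0;
  double aligned = 0.0;
  const int R = (int)ridx.size();
  for (int k = 0; k < R; ++k) {
    double s = x[ridx[k]];
    if (rstate[k] * s > 0 && std::fabs(s) >= min_mag) ++nsat;
    aligned += rstate[k] * s;
  }
  if (nsat_out) *nsat_out = nsat;
  return (double)nsat + 0.99 * 0.5 * (aligned / R + 1.0);
}

// Simulated-annealing fit of edge weights against node restrictions.
// Weight moves perturb one uniformly chosen edge by a Gaussian step and
// clip to that edge's allowed interval [lo, hi]; acceptance is by the
// Metropolis rule on the objective. Search propagations warm-start from
// the current fixed point; the returned signals come from a cold-start
// propagation of the best weights so they match propagate() exactly.
// [[Rcpp::export]]
List cpp_anneal(int n, IntegerVector src, IntegerVector dst,
                NumericVector lo, NumericVector hi,
                IntegerVector clamp_idx, NumericVector clamp_val,
                IntegerVector restr_idx, NumericVector restr_state,
                double min_mag, double t0, double cooling,
                int steps_per_t, int n_temps, double move_scale,
                int max_iter, double tol, double damping,
                unsigned int seed) {
  const int m = src.size();
  std::vector<int> s(src.begin(), src.end()), d(dst.begin(), dst.end());
  std::vector<int> ci(clamp_idx.begin(), clamp_idx.end());
  std::vector<double> cv(clamp_val.begin(), clamp_val.end());
  std::vector<int> ridx(restr_idx.begin(), restr_idx.end());
  std::vector<double> rstate(restr_state.begin(), restr_state.end());
  std::vector<double> wlo(lo.begin(), lo.end()), whi(hi.begin(), hi.end());

  RngMT rng(seed);
  std::vector<double> w(m);
  for (int l = 0; l < m; ++l)
    w[l] = wlo[l] + (whi[l] - wlo[l]) * rng.unif();

  // search propagations run at a coarser tolerance (warm-started from the
  // current fixed point); the returned solution is re-propagated below at
  // the full tolerance from a cold start.
  const double stol = tol * 100.0;
  const int R = (int)ridx.size();
  std::vector<double> x(n, 0.0);
  propagate_core(x, s, d, w, ci, cv, max_iter, stol, damping);
  int cur_nsat = 0;
  double cur = objective(x, ridx, rstate, min_mag, &cur_nsat);
  std::vector<double> wbest = w;
  double best = cur;
  bool solved = (cur_nsat == R);

  NumericVector trace(n_temps > 0 ? n_temps : 0);
  double T = t0;
  std::vector<double> xprev(n);
  for (int t = 0; t < n_temps && !solved; ++t) {
    for (int step = 0; step < steps_per_t; ++step) {
      int l = (int)(rng.unif() * m);
      if (l >= m) l = m - 1;
      double wold = w[l];
      double wnew = wold + move_scale * rng.gauss();
      if (wnew < wlo[l]) wnew = wlo[l];
      if (wnew > whi[l]) wnew = whi[l];
      w[l] = wnew;
      xprev = x;                           // warm start, revert on reject
      propagate_core(x, s, d, w, ci, cv, max_iter, stol, damping);
      int nsat = 0;
      double prop = objective(x, ridx, rstate, min_mag, &nsat);
      double delta = prop - cur;
      if (delta >= 0 || rng.unif() < std::exp(delta / T)) {
        cur = prop;
        cur_nsat = nsat;
        if (cur > best) { best = cur; wbest = w; }
        if (cur_nsat == R) { solved = true; break; }
      } else {
        w[l] = wold;
        x = xprev;
      }
    }
    if (n_temps > 0 && t < n_temps) trace[t] = best;
    T *= cooling;
  }
  if (solved) wbest = w;
  // running max keeps the trace well-defined for temperatures skipped by
  // the early exit
  for (int t = 1; t < n_temps; ++t)
    if (trace[t] < trace[t - 1]) trace[t] = trace[t - 1];

  // cold-start re-evaluation of the best weights
  std::vector<double> xb(n, 0.0);
  int it = propagate_core(xb, s, d, wbest, ci, cv, max_iter, tol, damping);
  int nsat = 0;
  objective(xb, ridx, rstate, min_mag, &nsat);
  return List::create(
    _["weights"] = NumericVector(wbest.begin(), wbest.end()),
    _["signals"] = NumericVector(xb.begin(), xb.end()),
    _["n_satisfied"] = nsat,
    _["accuracy"] = rstate.empty() ? NA_REAL : (double)nsat / rstate.size(),
    _["trace"] = trace,
    _["converged"] = (it > 0));
}
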