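// Compiled inner loop for the genotype-frequency recursion.
//
// The canonical, documented form of the one-generation map lives in
// R/model_core.R (step_generation); this file repeats it in C++ so that
// equilibration runs of up to millions of generations, bisection threshold
// searches and phase sweeps stay fast. A unit test asserts that the two
// implementations agree to machine precision.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// parameter vector layout (see params_vector() in R/params.R):
// 0:g 1:alpha 2:s 3:d 4:e_m 5:G_h 6:P_h 7:model

// One generation. Returns false (and leaves f untouched) when N_S = 0.
static bool step_once(double f[4], const double* p) {
  const double g = p[0], alpha = p[1], s = p[2], d = p[3], em = p[4],
               Gh = p[5], Ph = p[6];
  const int model = static_cast<int>(p[7]);

  const double pol_h = f[0] * Ph;
  const double pol_m = (f[1] + f[3] * (1.0 - em)) * alpha * Ph;
  const double P_bar = pol_h + pol_m;

  double P_X = 0.0, P_Y = 0.0, outx = 0.0;
  if (P_bar > 0.0) {
    P_X = (pol_h + 0.5 * pol_m) / P_bar;
    P_Y = 1.0 - P_X;
    outx = (model == 1) ? 1.0 : std::min(1.0, P_bar / Ph);
  }

  const double S1 = s * Gh * f[0];
  const double O_XXn = outx * (1.0 - s) * Gh * f[0];
  const double O_XXc = outx * g * Gh * f[2];
  const double S2 = (model == 3) ? (1.0 - outx) * (1.0 - s) * Gh * f[0] : 0.0;
  const double NS = O_XXn + O_XXc + (S1 + S2) * (1.0 - d);
  if (NS <= 0.0) return false;

  double nxt[4] = {
    (O_XXn * P_X + (S1 + S2) * (1.0 - d)) / NS,
    (O_XXn * P_Y) / NS,
    (O_XXc * P_X) / NS,
    (O_XXc * P_Y) / NS
  };
  double tot = 0.0;
  for (int i = 0; i < 4; ++i) {
    if (nxt[i] < 1e-15) nxt[i] = 0.0;
    tot += nxt[i];
  }
  for (int i = 0; i < 4; ++i) f[i] = nxt[i] / tot;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_step(NumericVector state, NumericVector par) {
  double f[4] = {state[0], state[1], state[2], state[3]};
  if (!step_once(f, par.begin()))
    stop("population produced no viable zygotes (N_S = 0)");
  return NumericVector::create(f[0], f[1], f[2], f[3]);
}

// Iterate until the L-infinity change over `window` generations drops below
// `tol`, extinction, `max_gen`, or (if stop_cms in [0,1]) until the CMS
// cytotype frequency reaches stop_cms. Returns the final state, the number
// of generations applied, and flags.
// [[Rcpp::export]]
List cpp_iterate(NumericVector state, NumericVector par,
                 double max_gen, double tol, int window,
                 double stop_cms) {
  double f[4] = {state[0], state[1], state[2], state[3]};
  const double* p = par.begin();
  std::vector<double> ring(4 * window);
  for (int i = 0; i < 4; ++i) ring[i] = f[i];

  bool converged = false, extinct = false, rescued = false;
  const long long gen_cap = static_cast<long long>(max_gen);
  long long gen = 0;
  while (gen < gen_cap) {
    if (!step_once(f, p)) { extinct = true; break; }
    ++gen;
    if (stop_cms >= 0.0 && f[2] + f[3] >= stop_cms) { rescued = true; break; }
    const int slot = 4 * static_cast<int>(gen % window);
    if (gen >= window) {
      double diff = 0.0;
      for (int i = 0; i < 4; ++i) {
        const double e = std::fabs(f[i] - ring[slot + i]);
        if (e > diff) diff = e;
      }
      if (diff < tol) { converged = true; }
    }
    for (int i = 0; i < 4; ++i) ring[slot + i] = f[i];
    if (converged) break;
    if ((gen & 0xFFFFF) == 0) checkUserInterrupt();
  }

  return List::create(
    _["state"] = NumericVector::create(f[0], f[1], f[2], f[3]),
    _["generations"] = static_cast<double>(gen),
    _["converged"] = converged,
    _["extinct"] = extinct,
    _["stopped_at_cms"] = rescued);
}

// Per-generation trajectory: (n_gen + 1) x 4 matrix including the initial
// state; truncated at extinction.
// [[Rcpp::export]]
NumericMatrix cpp_trajectory(NumericVector state, NumericVector par,
                             int n_gen) {
  NumericMatrix out(n_gen + 1, 4);
  double f[4] = {state[0], state[1], state[2], state[3]};
  const double* p = par.begin();
  for (int j = 0; j < 4; ++j) out(0, j) = f[j];
  int t = 1;
  for (; t <= n_gen; ++t) {
    if (!step_once(f, p)) break;
    for (int j = 0; j < 4; ++j) out(t, j) = f[j];
  }
  if (t <= n_gen) return out(Range(0, t - 1), Range(0, 3));
  return out;
}
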