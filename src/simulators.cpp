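// Euler-Maruyama time-stepping loops for the stochastic evidence
// accumulation models. All randomness comes from R's own RNG stream
// (unif_rand / norm_rand), so set.seed() in R controls the compiled loops
// and mixed R/C++ draw sequences stay reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Within-trial noise: either an exact normal draw, or a uniform integer
// index into the precomputed inverse-CDF look-up table.
struct Noise {
  const double* tab;
  int n;
  bool lut;
  Noise(const NumericVector& table, bool use_lut)
      : tab(table.begin()), n(table.size()), lut(use_lut) {}
  inline double operator()() {
    if (!lut) return norm_rand();
    int k = static_cast<int>(unif_rand() * n);
    if (k >= n) k = n - 1;  // unif_rand() can return 1.0 - eps exactly
    if (k < 0) k = 0;
    return tab[k];
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_diffusion_cpp(NumericVector v_trial, NumericVector z_trial,
                       double sigma, double h, int max_steps,
                       NumericVector upper, NumericVector lower,
                       NumericVector drift_profile, int swap_step,
                       NumericVector v2_trial, NumericVector table,
                       bool use_lut) {
  const int n = v_trial.size();
  IntegerVector resp(n), steps(n);
  Noise eps(table, use_lut);
  const double sq = sigma * std::sqrt(h);
  const bool tv = drift_profile.size() > 0;
  const bool pw = v2_trial.size() > 0;

  for (int i = 0; i < n; ++i) {
    double x = z_trial[i];
    int r = 0, s = 0;
    for (; s < max_steps; ++s) {
      double vt = tv ? drift_profile[s]
                     : ((pw && s >= swap_step) ? v2_trial[i] : v_trial[i]);
      x += vt * h + sq * eps();
      if (x >= upper[s]) { r = 1; break; }
      if (x <= lower[s]) { r = 2; break; }
    }
    resp[i] = r;
    steps[i] = (r == 0) ? max_steps : s + 1;
  }
  return List::create(_["resp"] = resp, _["steps"] = steps);
}

// [[Rcpp::export]]
List sim_lca_cpp(int n, NumericVector v_base, NumericVector v2_base,
                 int swap_step, NumericMatrix drift_mat,
                 NumericMatrix thresh_mat, double lam, double beta,
                 double sigma, double h, int max_steps, NumericVector table,
                 bool use_lut) {
  const int k = thresh_mat.ncol();
  IntegerVector resp(n), steps(n);
  Noise eps(table, use_lut);
  const double sq = sigma * std::sqrt(h);
  const bool tv = drift_mat.nrow() > 0;
  const bool pw = v2_base.size() > 0;
  std::vector<double> x(k), nx(k);

  for (int i = 0; i < n; ++i) {
    std::fill(x.begin(), x.end(), 0.0);
    int r = 0, s = 0;
    for (; s < max_steps && r == 0; ++s) {
      double total = 0.0;
      for (int j = 0; j < k; ++j) total += x[j];
      for (int j = 0; j < k; ++j) {
        double vt = tv ? drift_mat(s, j)
                       : ((pw && s >= swap_step) ? v2_base[j] : v_base[j]);
        double val = x[j] +
            (vt - lam * x[j] - beta * (total - x[j])) * h + sq * eps();
        nx[j] = (val < 0.0) ? 0.0 : val;  // reflecting floor, after noise
      }
      for (int j = 0; j < k; ++j) {
        x[j] = nx[j];
        if (r == 0 && x[j] >= thresh_mat(s, j)) r = j + 1;  // lowest index wins
      }
    }
    resp[i] = r;
    steps[i] = (r == 0) ? max_steps : s;  // s was incremented past the hit
  }
  return List::create(_["resp"] = resp, _["steps"] = steps);
}

// [[Rcpp::export]]
List sim_ugm_cpp(int n, double v, NumericVector drift_profile, double a,
                 double tau, double u_slope, double u_intercept, double sigma,
                 double h, int max_steps, NumericVector table, bool use_lut) {
  IntegerVector resp(n), steps(n);
  Noise eps(table, use_lut);
  const double inv_sqrt_h = 1.0 / std::sqrt(h);
  const double alpha = h / tau;
  const bool tv = drift_profile.size() > 0;

  for (int i = 0; i < n; ++i) {
    double E = 0.0;
    int r = 0, s = 0;
    for (; s < max_steps; ++s) {
      double vt = tv ? drift_profile[s] : v;
      double rin = vt + sigma * eps() * inv_sqrt_h;
      E += alpha * (rin - E);
      double t = (s + 1) * h;
      double y = E * (u_intercept + u_slope * 1000.0 * t);
      if (y >= a) { r = 1; break; }
      if (y <= -a) { r = 2; break; }
    }
    resp[i] = r;
    steps[i] = (r == 0) ? max_steps : s + 1;
  }
  return List::create(_["resp"] = resp, _["steps"] = steps);
}
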