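#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy (Richman & Moorman): B = template pairs of length m within
// Chebyshev distance r, A = pairs also matching at length m+1. Both counts
// run over the N-m templates, self-matches excluded. Returns -log(A/B); when
// A or B is zero, returns the finite-sample cap -log(2/((N-m-1)(N-m))).
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m; // number of templates of length m (and m+1 usable)
  if (nt < 2) stop("series too short for sample entropy");
  long long A = 0, B = 0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  double cap = -std::log(2.0 / ((double)(N - m - 1) * (double)(N - m)));
  if (A == 0 || B == 0) return cap;
  return -std::log((double)A / (double)B);
}

// Fuzzy entropy (Chen et al.): templates are mean-centred; a pair at
// Chebyshev distance d has membership exp(-d^n / r). phi_m is the average
// membership over all ordered pairs (equivalently unordered, it is
// symmetric); FuzzyEn = log(phi_m) - log(phi_{m+1}).
static double fuzzy_phi(const NumericVector& x, int m, double n_exp,
                        double r) {
  const int N = x.size();
  const int nt = N - m;
  // centred templates, nt x m
  std::vector<double> u((size_t)nt * m);
  for (int i = 0; i < nt; ++i) {
    double mu = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k];
    mu /= m;
    for (int k = 0; k < m; ++k) u[(size_t)i * m + k] = x[i + k] - mu;
  }
  // exp(-d^n/r) < 1e-18 contributes nothing at double precision
  const double dmax = std::pow(41.5 * r, 1.0 / n_exp);
  const bool sq = (n_exp == 2.0), lin = (n_exp == 1.0);
  const double inv_r = 1.0 / r;
  double sum = 0.0;
  for (int i = 0; i < nt; ++i) {
    const double* ui = &u[(size_t)i * m];
    for (int j = i + 1; j < nt; ++j) {
      const double* uj = &u[(size_t)j * m];
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(ui[k] - uj[k]);
        if (dd > d) d = dd;
      }
      if (d >= dmax) continue;
      double e = sq ? d * d : (lin ? d : std::pow(d, n_exp));
      sum += std::exp(-e * inv_r);
    }
  }
  return 2.0 * sum / ((double)nt * (double)(nt - 1));
}

// [[Rcpp::export(name = ".fuzzyen_cpp")]]
double fuzzyen_cpp(NumericVector x, int m, double n_exp, double r) {
  const int N = x.size();
  if (N - m - 1 < 2) stop("series too short for fuzzy entropy");
  double phi_m = fuzzy_phi(x, m, n_exp, r);
  double phi_m1 = fuzzy_phi(x, m + 1, n_exp, r);
  if (phi_m <= 0.0 || phi_m1 <= 0.0)
    return std::log((double)(N - m - 1) * (double)(N - m) / 2.0);
  return std::log(phi_m) - std::log(phi_m1);
}
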