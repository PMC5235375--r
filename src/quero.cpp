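#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Cascade of biquad sections in direct form II transposed.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// [[Rcpp::export]]
NumericVector sos_filter_cpp(NumericVector x, NumericMatrix sos) {
  int n = x.size(), ns = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Exact one-sided p-value for Spearman's rho (no ties), alternative "less":
// P(D >= d_obs) where D = sum of squared rank differences, by full
// enumeration of the n! rank permutations. Feasible for n <= 10.
// [[Rcpp::export]]
double spearman_exact_p_cpp(int n, double d_obs) {
  std::vector<int> perm(n);
  std::iota(perm.begin(), perm.end(), 1);
  long double count = 0.0L, total = 0.0L;
  do {
    double d = 0.0;
    for (int i = 0; i < n; ++i) {
      double diff = perm[i] - (i + 1);
      d += diff * diff;
    }
    if (d >= d_obs - 1e-9) count += 1.0L;
    total += 1.0L;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return (double)(count / total);
}
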