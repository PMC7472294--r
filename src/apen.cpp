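#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mean log correlation integral at embedding dimension m with Chebyshev
// distance and tolerance r. Self-matches are included (every count >= 1,
// so the log is always defined) and the pairwise distance matrix is
// symmetric, so each unordered pair is tested once.
static double phi_m(const double* x, int n, int m, double r) {
  const int nv = n - m + 1;
  std::vector<int> count(nv, 1);
  for (int k = 0; k < nv; ++k) {
    const double* xk = x + k;
    for (int j = k + 1; j < nv; ++j) {
      const double* xj = x + j;
      bool within = true;
      for (int i = 0; i < m; ++i) {
        double d = xk[i] - xj[i];
        if (d > r || d < -r) { within = false; break; }
      }
      if (within) { ++count[k]; ++count[j]; }
    }
  }
  double acc = 0.0;
  for (int k = 0; k < nv; ++k)
    acc += std::log((double)count[k] / (double)nv);
  return acc / (double)nv;
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n < m + 2) stop("series too short for approximate entropy");
  const double* xp = REAL(x);
  return phi_m(xp, n, m, r) - phi_m(xp, n, m + 1, r);
}
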