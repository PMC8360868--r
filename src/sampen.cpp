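#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template-match pair counts for sample entropy (Richman & Moorman
// convention): B counts unordered pairs of distinct m-length templates
// within Chebyshev distance r (strict inequality), A the same for length
// m+1, both over the first N - m templates so the conditional probability
// A/B is well defined.  Self-matches are excluded.
//
// Pairs are enumerated through indices sorted by the first template
// coordinate: only pairs whose first coordinates differ by less than r
// can match, which prunes the quadratic scan by roughly 1/P(|dx| < r).
// Counts are exact integers returned as doubles (far below 2^53).
//
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of (m+1)-length templates
  long double A = 0.0L, B = 0.0L;
  if (nt < 2 || r <= 0.0) {
    return NumericVector::create(_["A"] = 0.0, _["B"] = 0.0);
  }
  const double *v = REAL(x);
  std::vector<int> idx(nt);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [v](int a, int b) { return v[a] < v[b]; });
  for (int a = 0; a < nt - 1; ++a) {
    const int i = idx[a];
    const double vi = v[i];
    for (int b = a + 1; b < nt; ++b) {
      const int j = idx[b];
      if (v[j] - vi >= r) break;      // sorted: no later b can match
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(v[i + k] - v[j + k]) >= r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0L;
      if (std::fabs(v[i + m] - v[j + m]) < r) A += 1.0L;
    }
  }
  return NumericVector::create(_["A"] = (double)A, _["B"] = (double)B);
}
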