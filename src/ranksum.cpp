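#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Two-sided Wilcoxon rank-sum p-value per row of `x`; group A is the first
// n_a columns, group B the rest. Exact distribution (Rmath pwilcox) when both
// groups have <= exact_max observations and the row has no ties; otherwise a
// tie-corrected normal approximation with continuity correction. A row whose
// rank variance is zero (all values identical) gets p = 1.
// [[Rcpp::export]]
NumericVector rank_sum_rows_cpp(NumericMatrix x, int n_a, int exact_max = 10) {
  const int m = x.nrow(), n = x.ncol();
  const int n_b = n - n_a;
  if (n_a < 2 || n_b < 2)
    stop("both groups need at least 2 observations");
  NumericVector out(m);
  std::vector<double> v(n), rk(n);
  std::vector<int> idx(n);
  const double mu = n_a * (double)n_b / 2.0;

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) v[j] = x(i, j);
    std::iota(idx.begin(), idx.end(), 0);
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    double tie_sum = 0.0;
    bool ties = false;
    int j = 0;
    while (j < n) {
      int k = j;
      while (k + 1 < n && v[idx[k + 1]] == v[idx[j]]) ++k;
      const double r = (j + k) / 2.0 + 1.0;
      for (int l = j; l <= k; ++l) rk[idx[l]] = r;
      const int t = k - j + 1;
      if (t > 1) {
        ties = true;
        tie_sum += (double)t * t * t - t;
      }
      j = k + 1;
    }
    double r1 = 0.0;
    for (int c = 0; c < n_a; ++c) r1 += rk[c];
    const double u = r1 - n_a * (n_a + 1.0) / 2.0;

    double p;
    if (!ties && n_a <= exact_max && n_b <= exact_max) {
      if (u > mu)
        p = R::pwilcox(u - 1, n_a, n_b, 0, 0);
      else
        p = R::pwilcox(u, n_a, n_b, 1, 0);
      p = std::min(1.0, 2.0 * p);
    } else {
      const double nn = n;
      const double s2 =
          (n_a * (double)n_b / 12.0) *
          ((nn + 1.0) - tie_sum / (nn * (nn - 1.0)));
      if (s2 <= 0.0) {
        out[i] = 1.0;
        continue;
      }
      double z = u - mu;
      const double corr = (z > 0) - (z < 0);
      z = (z - 0.5 * corr) / std::sqrt(s2);
      const double pl = R::pnorm(z, 0.0, 1.0, 1, 0);
      const double pg = R::pnorm(z, 0.0, 1.0, 0, 0);
      p = std::min(1.0, 2.0 * std::min(pl, pg));
    }
    out[i] = p;
  }
  return out;
}
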