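#include <Rcpp.h>
#include <vector>
#include <cmath>

// Exact 1-D k-means by dynamic programming over the sorted input.
// The optimal 1-D partition is contiguous in sorted order, so
// D[m][i] = min_j { D[m-1][j-1] + ss(j..i) } with ss the within-block sum of
// squares, computed in O(1) from prefix sums.  O(k n^2) time, deterministic.

// [[Rcpp::export]]
Rcpp::IntegerVector kmeans1d_assign(Rcpp::NumericVector x, int k) {
  const int n = x.size();
  if (k < 1 || k > n) Rcpp::stop("k must be between 1 and length(x)");
  for (int i = 1; i < n; ++i)
    if (x[i] < x[i - 1]) Rcpp::stop("x must be sorted ascending");

  std::vector<long double> s1(n + 1, 0.0L), s2(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + (long double)x[i];
    s2[i + 1] = s2[i] + (long double)x[i] * x[i];
  }
  // ss of x[j..i], 1-based inclusive
  auto ss = [&](int j, int i) -> long double {
    long double sum = s1[i] - s1[j - 1];
    long double sq = s2[i] - s2[j - 1];
    int m = i - j + 1;
    return sq - sum * sum / m;
  };

  const long double INF = 1e300L;
  std::vector<std::vector<long double>> D(k + 1,
      std::vector<long double>(n + 1, INF));
  std::vector<std::vector<int>> back(k + 1, std::vector<int>(n + 1, 0));
  D[0][0] = 0.0L;
  for (int m = 1; m <= k; ++m) {
    for (int i = m; i <= n; ++i) {
      long double best = INF;
      int bestj = m;
      for (int j = m; j <= i; ++j) {
        if (D[m - 1][j - 1] >= INF) continue;
        long double cand = D[m - 1][j - 1] + ss(j, i);
        if (cand < best) { // strict: ties keep the smallest j scanned first
          best = cand;
          bestj = j;
        }
      }
      D[m][i] = best;
      back[m][i] = bestj;
    }
  }

  Rcpp::IntegerVector cl(n);
  int i = n;
  for (int m = k; m >= 1; --m) {
    int j = back[m][i];
    for (int t = j; t <= i; ++t) cl[t - 1] = m;
    i = j - 1;
  }
  return cl;
}
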