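// Minimum-cost assignment (Jonker-Volgenant style shortest augmenting paths)
// used by the evaluator's one-to-one water matching: edges above the cutoff
// carry a large penalty, so the optimum maximizes matched pairs first and
// minimizes total distance among maximum matchings.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// cost must have n_rows <= n_cols; returns the 1-based column assigned to
// each row.
// [[Rcpp::export]]
arma::ivec cpp_assignment(const arma::mat& cost) {
  const int n = cost.n_rows, m = cost.n_cols;
  if (n > m) Rcpp::stop("cpp_assignment: need n_rows <= n_cols");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> match(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    match[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = match[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) {
          minv[j] = cur;
          way[j] = j0;
        }
        if (minv[j] < delta) {
          delta = minv[j];
          j1 = j;
        }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) {
          u[match[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (match[j0] != 0);
    do {
      int j1 = way[j0];
      match[j0] = match[j1];
      j0 = j1;
    } while (j0);
  }
  arma::ivec ans(n);
  for (int j = 1; j <= m; ++j)
    if (match[j]) ans(match[j] - 1) = j;
  return ans;
}
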