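#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Minimum-cost rectangular assignment (n rows <= m columns) by shortest
// augmenting paths (Hungarian / Jonker-Volgenant family, O(n^2 m)).
// Every row is assigned to a distinct column. Deterministic: the scan
// order over columns is fixed, so ties always resolve to the lowest
// column index.
//
// cost: n x m matrix; entries may be large ("forbidden") but must be finite.
// Returns a 1-based column index for every row.
// [[Rcpp::export]]
IntegerVector solveAssignment(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (m < n) stop("cost matrix needs at least as many columns as rows");
  if (n == 0) return IntegerVector(0);

  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, R_PosInf);
    std::vector<bool> used(m + 1, false);
    do {
      used[j0] = true;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = R_PosInf;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }

  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
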