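#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Normalized local contrast of the 2-px-wide annulus starting `gap` px
// outside a connected component: sd of the frame intensities over pixels
// whose distance to the component lies in (gap, gap+2], divided by `rng`
// (the frame intensity range). rr/cc are the component's 1-based raster
// coordinates. Returns 0 for degenerate neighborhoods.
// [[Rcpp::export]]
double annulusContrastCpp(NumericMatrix frame, IntegerVector rr,
                          IntegerVector cc, double gap, double rng) {
  if (rng <= 0.0) return 0.0;
  const int H = frame.nrow(), W = frame.ncol();
  const int n = rr.size();
  int rmin = H, rmax = 1, cmin = W, cmax = 1;
  for (int i = 0; i < n; ++i) {
    if (rr[i] < rmin) rmin = rr[i];
    if (rr[i] > rmax) rmax = rr[i];
    if (cc[i] < cmin) cmin = cc[i];
    if (cc[i] > cmax) cmax = cc[i];
  }
  const int pad = (int)std::ceil(gap + 2.0) + 1;
  const int r0 = std::max(1, rmin - pad), r1 = std::min(H, rmax + pad);
  const int c0 = std::max(1, cmin - pad), c1 = std::min(W, cmax + pad);
  const int nr = r1 - r0 + 1, nc = c1 - c0 + 1;

  std::vector<char> comp(nr * nc, 0);
  for (int i = 0; i < n; ++i)
    comp[(cc[i] - c0) * nr + (rr[i] - r0)] = 1;

  // boundary pixels of the component (4-neighbour)
  std::vector<int> br, bc;
  for (int i = 0; i < n; ++i) {
    const int r = rr[i] - r0, c = cc[i] - c0;
    bool interior = r > 0 && r < nr - 1 && c > 0 && c < nc - 1 &&
                    comp[(c - 1) * nr + r] && comp[(c + 1) * nr + r] &&
                    comp[c * nr + r - 1] && comp[c * nr + r + 1];
    if (!interior) { br.push_back(r); bc.push_back(c); }
  }

  const double lo2 = gap * gap, hi = gap + 2.0, hi2 = hi * hi;
  double s = 0.0, s2 = 0.0;
  int cnt = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (comp[c * nr + r]) continue;
      double best = 1e18;
      for (size_t k = 0; k < br.size(); ++k) {
        const double dr = r - br[k], dc = c - bc[k];
        const double d2 = dr * dr + dc * dc;
        if (d2 < best) best = d2;
      }
      if (best > lo2 && best <= hi2) {
        const double v = frame(r0 - 1 + r, c0 - 1 + c);
        s += v; s2 += v * v; ++cnt;
      }
    }
  }
  if (cnt < 2) return 0.0;
  const double var = (s2 - s * s / cnt) / (cnt - 1);
  return var > 0.0 ? std::sqrt(var) / rng : 0.0;
}
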