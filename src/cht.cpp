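#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Vote accumulation for one candidate radius of the circle Hough
// transform, followed by 3x3 box pooling.  Each edge pixel (1-based
// row ey, column ex) votes at the two centre candidates displaced +/- r_px
// along its gradient direction (uy, ux), with weight w.  Pooling absorbs
// the rounding of sub-pixel centres.
// [[Rcpp::export]]
NumericMatrix cht_vote_pool(IntegerVector ey, IntegerVector ex,
                            NumericVector uy, NumericVector ux,
                            NumericVector w, double r_px, int H, int W) {
  std::vector<double> acc((size_t)H * W, 0.0);
  const int n = ey.size();
  for (int s = -1; s <= 1; s += 2) {
    for (int i = 0; i < n; ++i) {
      int cy = (int)std::lround(ey[i] + s * r_px * uy[i]);
      int cx = (int)std::lround(ex[i] + s * r_px * ux[i]);
      if (cy < 1 || cy > H || cx < 1 || cx > W) continue;
      acc[(size_t)(cx - 1) * H + (cy - 1)] += w[i];
    }
  }
  // separable 3x3 box sum (zero padding)
  std::vector<double> tmp((size_t)H * W);
  for (int c = 0; c < W; ++c) {
    const double* col = &acc[(size_t)c * H];
    double* out = &tmp[(size_t)c * H];
    for (int r = 0; r < H; ++r) {
      double v = col[r];
      if (r > 0) v += col[r - 1];
      if (r < H - 1) v += col[r + 1];
      out[r] = v;
    }
  }
  NumericMatrix res(H, W);
  double* rp = REAL(res);
  for (int c = 0; c < W; ++c) {
    const double* c0 = &tmp[(size_t)c * H];
    const double* cm = c > 0 ? &tmp[(size_t)(c - 1) * H] : 0;
    const double* cp = c < W - 1 ? &tmp[(size_t)(c + 1) * H] : 0;
    double* out = rp + (size_t)c * H;
    for (int r = 0; r < H; ++r) {
      double v = c0[r];
      if (cm) v += cm[r];
      if (cp) v += cp[r];
      out[r] = v;
    }
  }
  return res;
}
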