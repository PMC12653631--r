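// Batched im2col for same-padding stride-1 convolutions.
//
// Input: an H x W x C x B array (column-major, as R stores it) and an odd
// kernel size k. Output: the (H*W*B) x (k*k*C) patch matrix whose rows are
// ordered pixel-fastest then image, and whose columns are ordered
// row-offset fastest, then column offset, then channel -- the layout the R
// conv layers multiply against their (k*k*C) x F weight matrices.
// Out-of-image taps are zero (implicit zero padding).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_batch_cpp(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected an H x W x C x B array");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int p = (k - 1) / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t rows = HW * B;
  NumericMatrix out(rows, (R_xlen_t)k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();

  R_xlen_t col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        double* dst = op + col * rows;
        const int oi = di - p, oj = dj - p;
        for (int b = 0; b < B; ++b) {
          const double* img = xp + ((R_xlen_t)b * C + c) * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + oj;
            double* drow = dst + (R_xlen_t)b * HW + (R_xlen_t)j * H;
            if (sj < 0 || sj >= W) {
              for (int i = 0; i < H; ++i) drow[i] = 0.0;
              continue;
            }
            const double* src = img + (R_xlen_t)sj * H;
            const int lo = std::max(0, -oi);
            const int hi = std::min(H, H - oi);
            for (int i = 0; i < lo; ++i) drow[i] = 0.0;
            for (int i = lo; i < hi; ++i) drow[i] = src[i + oi];
            for (int i = hi; i < H; ++i) drow[i] = 0.0;
          }
        }
      }
    }
  }
  return out;
}
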