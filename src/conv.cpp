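// im2col / col2im kernels for the 3x3 zero-padded convolutions.
// Layout contract (shared with R/layers.R): output pixels ordered
// column-major over (Ho, Wo); column block for channel c occupies columns
// c*9 + k with kernel offset k = dj*3 + di (di = row offset, fastest).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int stride) {
  const int Ho = (H - 1) / stride + 1, Wo = (W - 1) / stride + 1;
  const int n = Ho * Wo;
  NumericMatrix col(n, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[(R_xlen_t)c * H * W];
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int k = dj * 3 + di;
        double* out = &col(0, c * 9 + k);
        for (int oj = 0; oj < Wo; ++oj) {
          const int jc = oj * stride + dj - 1;
          if (jc < 0 || jc >= W) continue;  // column stays zero
          const double* xcol = xc + (R_xlen_t)jc * H;
          double* ocol = out + (R_xlen_t)oj * Ho;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ir = oi * stride + di - 1;
            if (ir >= 0 && ir < H) ocol[oi] = xcol[ir];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, int H, int W, int C, int stride) {
  const int Ho = (H - 1) / stride + 1, Wo = (W - 1) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    double* dxc = &dx[(R_xlen_t)c * H * W];
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int k = dj * 3 + di;
        const double* src = &dcol(0, c * 9 + k);
        for (int oj = 0; oj < Wo; ++oj) {
          const int jc = oj * stride + dj - 1;
          if (jc < 0 || jc >= W) continue;
          const double* scol = src + (R_xlen_t)oj * Ho;
          double* dxcol = dxc + (R_xlen_t)jc * H;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ir = oi * stride + di - 1;
            if (ir >= 0 && ir < H) dxcol[ir] += scol[oi];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
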