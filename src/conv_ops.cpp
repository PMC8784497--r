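// Patch gather/scatter kernels for the 2D convolutions of the slice
// segmenter. Layout contract (column-major, matching the R arrays):
//   padded input xp: (hp, wp, c)
//   patch matrix X:  (ho*wo) rows, (kh*kw*c) columns; rows ordered with
//     the output row index fastest; columns grouped per kernel offset
//     (ki fastest, then kj), channel-fastest within a group.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector xp, int hp, int wp, int c,
                         int kh, int kw, int stride) {
  const int ho = (hp - kh) / stride + 1;
  const int wo = (wp - kw) / stride + 1;
  const int n = ho * wo;
  NumericMatrix X(n, kh * kw * c);
  const double *src0 = xp.begin();
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      const int blk = (kj * kh + ki) * c;
      for (int ch = 0; ch < c; ++ch) {
        double *dst = &X(0, blk + ch);
        const double *plane = src0 + (R_xlen_t)ch * hp * wp;
        for (int ow = 0; ow < wo; ++ow) {
          const double *col = plane + (R_xlen_t)(ow * stride + kj) * hp + ki;
          double *d = dst + (R_xlen_t)ow * ho;
          for (int oh = 0; oh < ho; ++oh)
            d[oh] = col[(R_xlen_t)oh * stride];
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dX, int hp, int wp, int c,
                         int kh, int kw, int stride) {
  const int ho = (hp - kh) / stride + 1;
  const int wo = (wp - kw) / stride + 1;
  NumericVector dxp((R_xlen_t)hp * wp * c);
  double *out0 = dxp.begin();
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      const int blk = (kj * kh + ki) * c;
      for (int ch = 0; ch < c; ++ch) {
        const double *src = &dX(0, blk + ch);
        double *plane = out0 + (R_xlen_t)ch * hp * wp;
        for (int ow = 0; ow < wo; ++ow) {
          double *col = plane + (R_xlen_t)(ow * stride + kj) * hp + ki;
          const double *s = src + (R_xlen_t)ow * ho;
          for (int oh = 0; oh < ho; ++oh)
            col[(R_xlen_t)oh * stride] += s[oh];
        }
      }
    }
  }
  return dxp;
}
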