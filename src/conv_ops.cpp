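#include <Rcpp.h>
using namespace Rcpp;

// im2col for 1-D convolution with "same" zero padding over a
// [C x T x B] array: output is [C*k x T*B], column (t, b), row-block j
// holding the input at temporal offset j - 1 - floor((k-1)/2).

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector x, int C, int T, int B, int k) {
  int pl = (k - 1) / 2;
  NumericMatrix col(C * k, T * B);
  const double *px = x.begin();
  double *pc = col.begin();
  int nrow = C * k;
  for (int b = 0; b < B; ++b) {
    const double *xb = px + (R_xlen_t)b * C * T;
    for (int t = 0; t < T; ++t) {
      double *cc = pc + (R_xlen_t)(b * T + t) * nrow;
      for (int j = 0; j < k; ++j) {
        int tt = t + j - pl;
        if (tt >= 0 && tt < T) {
          const double *src = xb + (R_xlen_t)tt * C;
          double *dst = cc + j * C;
          for (int c = 0; c < C; ++c) dst[c] = src[c];
        }
      }
    }
  }
  return col;
}

// adjoint of im2col: scatter-add the column gradient back onto the
// [C x T x B] input gradient

// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix dcol, int C, int T, int B, int k) {
  int pl = (k - 1) / 2;
  NumericVector dx((R_xlen_t)C * T * B);
  dx.attr("dim") = IntegerVector::create(C, T, B);
  double *pdx = dx.begin();
  const double *pc = dcol.begin();
  int nrow = C * k;
  for (int b = 0; b < B; ++b) {
    double *xb = pdx + (R_xlen_t)b * C * T;
    for (int t = 0; t < T; ++t) {
      const double *cc = pc + (R_xlen_t)(b * T + t) * nrow;
      for (int j = 0; j < k; ++j) {
        int tt = t + j - pl;
        if (tt >= 0 && tt < T) {
          double *dst = xb + (R_xlen_t)tt * C;
          const double *src = cc + j * C;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  return dx;
}
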