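#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as R arrays with dim c(C, H, W): channel fastest,
// then row (height), then column (width).
//
// im2col lays out one column per output pixel (ho fastest, then wo), and one
// row per (c, ki, kj) with c fastest, then kernel row ki, then kernel col kj.
// This matches matrix(w, nrow = Cout) flattening of a weight array
// dim c(Cout, Cin, kh, kw), so conv forward is a single matrix product.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W,
                         int kh, int kw, int stride, int pad, int dil) {
  int Ho = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  int Wo = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  NumericMatrix out(C * kh * kw, Ho * Wo);
  const double* px = x.begin();
  double* po = out.begin();
  int nrow = C * kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      double* colp = po + (R_xlen_t)col * nrow;
      for (int kj = 0; kj < kw; ++kj) {
        int wi = wo * stride - pad + kj * dil;
        for (int ki = 0; ki < kh; ++ki) {
          int hi = ho * stride - pad + ki * dil;
          int r0 = C * (ki + kh * kj);
          if (hi < 0 || hi >= H || wi < 0 || wi >= W) {
            for (int c = 0; c < C; ++c) colp[r0 + c] = 0.0;
          } else {
            const double* src = px + (R_xlen_t)C * (hi + (R_xlen_t)H * wi);
            for (int c = 0; c < C; ++c) colp[r0 + c] = src[c];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into the input layout.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W,
                         int kh, int kw, int stride, int pad, int dil) {
  int Ho = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  int Wo = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W);
  double* px = x.begin();
  const double* po = cols.begin();
  int nrow = C * kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      const double* colp = po + (R_xlen_t)col * nrow;
      for (int kj = 0; kj < kw; ++kj) {
        int wi = wo * stride - pad + kj * dil;
        for (int ki = 0; ki < kh; ++ki) {
          int hi = ho * stride - pad + ki * dil;
          if (hi < 0 || hi >= H || wi < 0 || wi >= W) continue;
          int r0 = C * (ki + kh * kj);
          double* dst = px + (R_xlen_t)C * (hi + (R_xlen_t)H * wi);
          for (int c = 0; c < C; ++c) dst[c] += colp[r0 + c];
        }
      }
    }
  }
  return x;
}
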