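#include <Rcpp.h>
using namespace Rcpp;

// Image batches travel through the network as channels-first matrices of
// shape (C) x (H*W*N): element (c, h + H*(w + W*n)). This keeps convolution
// outputs (one row per output channel) directly consumable by per-channel
// batch normalisation and bias addition without any transposition.
//
// im2col lowers sliding k x k windows (stride s, zero-pad p) into a
// (k*k*C) x (oH*oW*N) matrix so convolution becomes one GEMM.
// Column order: oh fastest, then ow, then n. Row order: kh fastest,
// then kw, then c.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix x, int H, int W, int N,
                         int k, int stride, int pad) {
  int C = x.nrow();
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, oH * oW * N);
  double *po = out.begin();
  double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        R_xlen_t col = (R_xlen_t)n * oH * oW + (R_xlen_t)ow * oH + oh;
        double *pc = po + col * (k * k * C);
        int h0 = oh * stride - pad;
        int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            int w = w0 + kw;
            if (w < 0 || w >= W) {
              for (int kh = 0; kh < k; ++kh) pc[kw * k + kh] = 0.0;
              continue;
            }
            double *pxw = px + c + (R_xlen_t)C * (H * ((R_xlen_t)W * n + w));
            for (int kh = 0; kh < k; ++kh) {
              int h = h0 + kh;
              pc[kw * k + kh] = (h < 0 || h >= H) ? 0.0 : pxw[(R_xlen_t)C * h];
            }
          }
          pc += k * k;
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back onto the channels-first grid,
// returning a (C) x (H*W*N) matrix.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix x(C, (R_xlen_t)H * W * N);
  double *px = x.begin();
  double *po = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        R_xlen_t col = (R_xlen_t)n * oH * oW + (R_xlen_t)ow * oH + oh;
        double *pc = po + col * (k * k * C);
        int h0 = oh * stride - pad;
        int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            double *pxw = px + c + (R_xlen_t)C * (H * ((R_xlen_t)W * n + w));
            for (int kh = 0; kh < k; ++kh) {
              int h = h0 + kh;
              if (h >= 0 && h < H) pxw[(R_xlen_t)C * h] += pc[kw * k + kh];
            }
          }
          pc += k * k;
        }
      }
    }
  }
  return x;
}
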