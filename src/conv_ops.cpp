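#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as (H*W*B) x C matrices, row index r = h + H*w + H*W*b
// (0-based), so the spatial grid of every image in the batch is column-major
// within its block of H*W rows. Convolutions use "same" zero padding and odd
// kernel sizes; the heavy lifting (the GEMM against the weight matrix) is done
// in R with BLAS, these kernels only gather/scatter patches.

// [[Rcpp::export]]
NumericMatrix im2col_same(const NumericMatrix& x, int H, int W, int B, int k) {
  const int C = x.ncol();
  const int pad = (k - 1) / 2;
  const int HW = H * W;
  NumericMatrix out(HW * B, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int q = kh + k * kw + k * k * c;
        double* dst = &out(0, q);
        const double* src = &x(0, c);
        for (int b = 0; b < B; ++b) {
          const int off = HW * b;
          for (int w = 0; w < W; ++w) {
            const int iw = w + kw - pad;
            if (iw < 0 || iw >= W) continue;
            const int ih0 = kh - pad;
            int h_lo = ih0 < 0 ? -ih0 : 0;
            int h_hi = (H - 1 + ih0 >= H) ? H - ih0 : H;  // exclusive
            const double* scol = src + off + H * iw + ih0;
            double* dcol = dst + off + H * w;
            for (int h = h_lo; h < h_hi; ++h) dcol[h] = scol[h];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_same: scatter-add patch gradients back onto the image grid.
// [[Rcpp::export]]
NumericMatrix col2im_same(const NumericMatrix& xcol, int H, int W, int B, int C,
                          int k) {
  const int pad = (k - 1) / 2;
  const int HW = H * W;
  NumericMatrix out(HW * B, C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int q = kh + k * kw + k * k * c;
        const double* src = &xcol(0, q);
        double* dst = &out(0, c);
        for (int b = 0; b < B; ++b) {
          const int off = HW * b;
          for (int w = 0; w < W; ++w) {
            const int iw = w + kw - pad;
            if (iw < 0 || iw >= W) continue;
            const int ih0 = kh - pad;
            int h_lo = ih0 < 0 ? -ih0 : 0;
            int h_hi = (H - 1 + ih0 >= H) ? H - ih0 : H;
            double* dcol = dst + off + H * iw + ih0;
            const double* scol = src + off + H * w;
            for (int h = h_lo; h < h_hi; ++h) dcol[h] += scol[h];
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled values and, per output cell and
// channel, the 1-based input row index of the argmax (first maximum on ties).
// [[Rcpp::export]]
List maxpool2_fw(const NumericMatrix& x, int H, int W, int B) {
  const int C = x.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const int HWo = Ho * Wo;
  NumericMatrix val(HWo * B, C);
  IntegerMatrix idx(HWo * B, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &x(0, c);
    for (int b = 0; b < B; ++b) {
      const int ioff = H * W * b, ooff = HWo * b;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int best = ioff + (2 * ho) + H * (2 * wo);
          double bv = src[best];
          const int cand[3] = {ioff + (2 * ho + 1) + H * (2 * wo),
                               ioff + (2 * ho) + H * (2 * wo + 1),
                               ioff + (2 * ho + 1) + H * (2 * wo + 1)};
          for (int j = 0; j < 3; ++j)
            if (src[cand[j]] > bv) { bv = src[cand[j]]; best = cand[j]; }
          const int orow = ooff + ho + Ho * wo;
          val(orow, c) = bv;
          idx(orow, c) = best + 1;
        }
      }
    }
  }
  return List::create(_["values"] = val, _["idx"] = idx);
}

// Scatter values (or gradients) to recorded argmax rows: max-unpooling forward
// and max-pooling backward are the same routing operation.
// [[Rcpp::export]]
NumericMatrix pool_scatter(const NumericMatrix& y, const IntegerMatrix& idx,
                           int n_rows) {
  const int C = y.ncol(), n = y.nrow();
  NumericMatrix out(n_rows, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < n; ++r) out(idx(r, c) - 1, c) += y(r, c);
  return out;
}

// Gather from recorded argmax rows: max-unpooling backward.
// [[Rcpp::export]]
NumericMatrix pool_gather(const NumericMatrix& big, const IntegerMatrix& idx) {
  const int C = idx.ncol(), n = idx.nrow();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < n; ++r) out(r, c) = big(idx(r, c) - 1, c);
  return out;
}
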