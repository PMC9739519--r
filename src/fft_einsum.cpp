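#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Per-frequency channel contractions for the FFT-domain convolution.
// Spectra are stored as nP x (B*C) complex matrices (batch fastest) and
// kernel spectra as nP x (C*F) (input channel fastest).

// y[p, (f)B+b] = sum_c x[p, (c)B+b] * k[p, (f)C+c]
// [[Rcpp::export]]
ComplexMatrix fft_conv_accum(const ComplexMatrix& x, const ComplexMatrix& k,
                             int B, int C, int F) {
  const int nP = x.nrow();
  ComplexMatrix y(nP, B * F);
  const std::complex<double>* xp =
      reinterpret_cast<const std::complex<double>*>(&x[0]);
  const std::complex<double>* kp =
      reinterpret_cast<const std::complex<double>*>(&k[0]);
  std::complex<double>* yp = reinterpret_cast<std::complex<double>*>(&y[0]);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c) {
      const std::complex<double>* kcol = kp + (size_t)nP * (f * C + c);
      for (int b = 0; b < B; ++b) {
        const std::complex<double>* xcol = xp + (size_t)nP * (c * B + b);
        std::complex<double>* ycol = yp + (size_t)nP * (f * B + b);
        for (int p = 0; p < nP; ++p) ycol[p] += xcol[p] * kcol[p];
      }
    }
  return y;
}

// dx[p, (c)B+b] = sum_f dy[p, (f)B+b] * k[p, (f)C+c]
// [[Rcpp::export]]
ComplexMatrix fft_convT_accum(const ComplexMatrix& dy, const ComplexMatrix& k,
                              int B, int C, int F) {
  const int nP = dy.nrow();
  ComplexMatrix dx(nP, B * C);
  const std::complex<double>* dp =
      reinterpret_cast<const std::complex<double>*>(&dy[0]);
  const std::complex<double>* kp =
      reinterpret_cast<const std::complex<double>*>(&k[0]);
  std::complex<double>* xp = reinterpret_cast<std::complex<double>*>(&dx[0]);
  for (int c = 0; c < C; ++c)
    for (int f = 0; f < F; ++f) {
      const std::complex<double>* kcol = kp + (size_t)nP * (f * C + c);
      for (int b = 0; b < B; ++b) {
        const std::complex<double>* dcol = dp + (size_t)nP * (f * B + b);
        std::complex<double>* xcol = xp + (size_t)nP * (c * B + b);
        for (int p = 0; p < nP; ++p) xcol[p] += dcol[p] * kcol[p];
      }
    }
  return dx;
}

// dw[p, (f)C+c] = sum_b conj(dy[p, (f)B+b]) * x[p, (c)B+b]
// [[Rcpp::export]]
ComplexMatrix fft_corr_accum(const ComplexMatrix& dy, const ComplexMatrix& x,
                             int B, int C, int F) {
  const int nP = dy.nrow();
  ComplexMatrix dw(nP, C * F);
  const std::complex<double>* dp =
      reinterpret_cast<const std::complex<double>*>(&dy[0]);
  const std::complex<double>* xp =
      reinterpret_cast<const std::complex<double>*>(&x[0]);
  std::complex<double>* wp = reinterpret_cast<std::complex<double>*>(&dw[0]);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c) {
      std::complex<double>* wcol = wp + (size_t)nP * (f * C + c);
      for (int b = 0; b < B; ++b) {
        const std::complex<double>* dcol = dp + (size_t)nP * (f * B + b);
        const std::complex<double>* xcol = xp + (size_t)nP * (c * B + b);
        for (int p = 0; p < nP; ++p)
          wcol[p] += std::conj(dcol[p]) * xcol[p];
      }
    }
  return dw;
}
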