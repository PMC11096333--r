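// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Zero-phase FIR filtering of the columns of X with a symmetric, odd-length
// kernel h. Each column is mirror-padded by (L-1)/2 samples on both sides,
// circularly convolved with the kernel via an FFT whose length is the next
// power of two >= padded length, and the central n samples are returned.
// Because the kernel is arranged symmetrically around lag zero its transfer
// function is real, so two real columns can be filtered per complex FFT by
// packing one into the real and one into the imaginary part.
//
// [[Rcpp::export]]
arma::mat fir_filter_cols(const arma::mat& X, const arma::vec& h,
                          const int block = 1024) {
  const int n = X.n_rows;
  const int ncol = X.n_cols;
  const int L = h.n_elem;
  if (L % 2 == 0) Rcpp::stop("FIR kernel must have odd length");
  const int pad = (L - 1) / 2;
  if (pad > n - 1)
    Rcpp::stop("epoch too short for kernel: %d-tap kernel needs %d samples of "
               "mirror padding but only %d are available",
               L, pad, n - 1);

  const int padded = n + 2 * pad;
  int nfft = 1;
  while (nfft < padded) nfft <<= 1;

  // zero-phase kernel layout: centre tap at index 0, negative lags wrapped
  cx_vec hbuf(nfft, fill::zeros);
  hbuf(0) = h(pad);
  for (int j = 1; j <= pad; ++j) {
    hbuf(j) = h(pad + j);
    hbuf(nfft - j) = h(pad - j);
  }
  vec H = real(fft(hbuf));  // imaginary part is zero by symmetry

  mat out(n, ncol);
  const int bl = std::max(2, block);
  for (int c0 = 0; c0 < ncol; c0 += bl) {
    const int nc = std::min(bl, ncol - c0);
    const int npair = (nc + 1) / 2;
    cx_mat Z(nfft, npair, fill::zeros);
    for (int p = 0; p < npair; ++p) {
      const int ca = c0 + 2 * p;
      const int cb = ca + 1;
      const bool has_b = (cb < c0 + nc);
      for (int i = 0; i < n; ++i)
        Z(pad + i, p) = std::complex<double>(X(i, ca),
                                             has_b ? X(i, cb) : 0.0);
      for (int j = 1; j <= pad; ++j) {  // mirror padding (no endpoint repeat)
        Z(pad - j, p) = std::complex<double>(X(j, ca),
                                             has_b ? X(j, cb) : 0.0);
        Z(pad + n - 1 + j, p) =
            std::complex<double>(X(n - 1 - j, ca),
                                 has_b ? X(n - 1 - j, cb) : 0.0);
      }
    }
    Z = fft(Z);
    Z.each_col() %= cx_vec(H, vec(nfft, fill::zeros));
    Z = ifft(Z);
    for (int p = 0; p < npair; ++p) {
      const int ca = c0 + 2 * p;
      const int cb = ca + 1;
      for (int i = 0; i < n; ++i) out(i, ca) = Z(pad + i, p).real();
      if (cb < c0 + nc)
        for (int i = 0; i < n; ++i) out(i, cb) = Z(pad + i, p).imag();
    }
  }
  return out;
}
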