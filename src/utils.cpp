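// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// per-column maximum absolute value and its row index (1-based)
// [[Rcpp::export]]
Rcpp::List col_abs_max_cpp(const arma::mat& X) {
  const int nc = X.n_cols, nr = X.n_rows;
  Rcpp::NumericVector mx(nc);
  Rcpp::IntegerVector ix(nc);
  for (int j = 0; j < nc; ++j) {
    double best = -1.0; int bi = 0;
    const double* col = X.colptr(j);
    for (int i = 0; i < nr; ++i) {
      const double a = std::fabs(col[i]);
      if (a > best) { best = a; bi = i; }
    }
    mx[j] = best; ix[j] = bi + 1;
  }
  return Rcpp::List::create(Rcpp::Named("max") = mx, Rcpp::Named("row") = ix);
}

// per-epoch peak |V| and its channel, over sample rows [r0, r1] of an
// n_samples x n_channels x n_epochs array (passed flat to avoid copies)
// [[Rcpp::export]]
Rcpp::List epoch_peaks_cpp(const Rcpp::NumericVector& arr, const int ns,
                           const int nc, const int ne, const int r0,
                           const int r1) {
  Rcpp::NumericVector peak(ne);
  Rcpp::IntegerVector chan(ne);
  const double* x = arr.begin();
  for (int e = 0; e < ne; ++e) {
    double best = -1.0; int bc = 0;
    for (int c = 0; c < nc; ++c) {
      const double* col = x + (static_cast<size_t>(e) * nc + c) * ns;
      for (int i = r0 - 1; i < r1; ++i) {
        const double a = std::fabs(col[i]);
        if (a > best) { best = a; bc = c; }
      }
    }
    peak[e] = best; chan[e] = bc + 1;
  }
  return Rcpp::List::create(Rcpp::Named("peak") = peak,
                            Rcpp::Named("channel") = chan);
}

// subtract per (channel, epoch) the mean over sample rows [r0, r1]
// [[Rcpp::export]]
Rcpp::NumericVector center_epochs_cpp(const Rcpp::NumericVector& arr,
                                      const int ns, const int ncols,
                                      const int r0, const int r1) {
  Rcpp::NumericVector out(Rcpp::clone(arr));
  double* x = out.begin();
  const int nbl = r1 - r0 + 1;
  for (int j = 0; j < ncols; ++j) {
    double* col = x + static_cast<size_t>(j) * ns;
    double s = 0.0;
    for (int i = r0 - 1; i < r1; ++i) s += col[i];
    const double mu = s / nbl;
    for (int i = 0; i < ns; ++i) col[i] -= mu;
  }
  out.attr("dim") = arr.attr("dim");
  return out;
}
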