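// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// L2-regularized L1-loss (hinge) linear SVM solved in the dual by
// coordinate descent (the LIBLINEAR dual CD scheme), with the bias folded
// into the weight vector through a constant augmented feature. Deterministic
// cyclic update order; problems here are tiny (tens of observations).
static vec train_binary_svm(const mat& Xa, const ivec& y, const double C,
                            const vec& Qii) {
  const int n = Xa.n_rows;
  const int d = Xa.n_cols;
  vec w(d, fill::zeros);
  vec alpha(n, fill::zeros);
  const int max_pass = 2000;
  const double tol = 1e-10;
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      if (Qii(i) <= 0.0) continue;
      const double G = y(i) * dot(w, Xa.row(i)) - 1.0;
      double PG = G;
      if (alpha(i) <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha(i) >= C && G < 0.0) PG = 0.0;
      if (std::abs(PG) > max_viol) max_viol = std::abs(PG);
      if (PG != 0.0) {
        const double a_old = alpha(i);
        double a_new = a_old - G / Qii(i);
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        if (a_new != a_old) {
          w += (a_new - a_old) * y(i) * Xa.row(i).t();
          alpha(i) = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
  return w;
}

// One-vs-Rest prediction: one binary machine per class, winner is the class
// with the largest decision value; exact ties go to the lowest class index.
static ivec ovr_predict(const mat& Xtr, const ivec& ytr, const mat& Xte,
                        const int n_class, const double C) {
  const int ntr = Xtr.n_rows;
  const int nte = Xte.n_rows;
  mat Xa(ntr, Xtr.n_cols + 1);
  Xa.cols(0, Xtr.n_cols - 1) = Xtr;
  Xa.col(Xtr.n_cols) = vec(ntr, fill::ones);
  mat Ta(nte, Xte.n_cols + 1);
  Ta.cols(0, Xte.n_cols - 1) = Xte;
  Ta.col(Xte.n_cols) = vec(nte, fill::ones);
  vec Qii = sum(square(Xa), 1);

  mat dec(nte, n_class);
  for (int c = 0; c < n_class; ++c) {
    ivec y(ntr);
    for (int i = 0; i < ntr; ++i) y(i) = (ytr(i) == c + 1) ? 1 : -1;
    const vec w = train_binary_svm(Xa, y, C, Qii);
    dec.col(c) = Ta * w;
  }
  ivec pred(nte);
  for (int i = 0; i < nte; ++i) {
    int best = 0;
    double bv = dec(i, 0);
    for (int c = 1; c < n_class; ++c)
      if (dec(i, c) > bv) { bv = dec(i, c); best = c; }
    pred(i) = best + 1;
  }
  return pred;
}

// [[Rcpp::export]]
arma::ivec ovr_svm_predict_cpp(const arma::mat& Xtr, const arma::ivec& ytr,
                               const arma::mat& Xte, const int n_class,
                               const double cost) {
  return ovr_predict(Xtr, ytr, Xte, n_class, cost);
}

// Cross-validated decoding across time points for one iteration.
// obs: cube of n_samples x n_channels x n_obs; cls/fold: per observation.
// Returns a matrix length(tidx) x n_folds of test accuracies.
// [[Rcpp::export]]
arma::mat decode_timepoints_cpp(const arma::cube& obs, const arma::ivec& cls,
                                const arma::ivec& fold, const arma::uvec& tidx,
                                const int n_class, const int n_folds,
                                const double cost, const bool standardize) {
  const int K = obs.n_slices;
  const int d = obs.n_cols;
  mat acc(tidx.n_elem, n_folds);
  mat Xt(K, d);
  for (uword ti = 0; ti < tidx.n_elem; ++ti) {
    const uword t = tidx(ti) - 1;  // 1-based from R
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < d; ++j) Xt(k, j) = obs(t, j, k);
    for (int f = 1; f <= n_folds; ++f) {
      const uvec itr = find(fold != f);
      const uvec ite = find(fold == f);
      mat Xtr = Xt.rows(itr);
      mat Xte = Xt.rows(ite);
      if (standardize) {
        const rowvec mu = mean(Xtr, 0);
        rowvec sd = stddev(Xtr, 0, 0);
        sd.replace(0.0, 1.0);
        Xtr.each_row() -= mu; Xtr.each_row() /= sd;
        Xte.each_row() -= mu; Xte.each_row() /= sd;
      }
      const ivec ytr = cls(itr);
      const ivec yte = cls(ite);
      const ivec pred = ovr_predict(Xtr, ytr, Xte, n_class, cost);
      int ok = 0;
      for (uword i = 0; i < ite.n_elem; ++i)
        if (pred(i) == yte(i)) ++ok;
      acc(ti, f - 1) = double(ok) / double(ite.n_elem);
    }
  }
  return acc;
}
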