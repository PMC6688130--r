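// Ridge-penalized logistic regression via Newton/IRLS.
//
// Minimizes  sum_i [ -y_i eta_i + log(1 + exp(eta_i)) ] + (lambda/2) ||w||^2
// with eta = b + X w; the intercept b is not penalized.  With lambda = 1/C
// this matches the usual C-parameterized L2-regularized logistic objective.
// Small dense problems only (n, p of order 10^2), called very many times
// inside leave-pair-out cross-validation, hence the compiled implementation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec irls_fit(const arma::mat& Xa, const arma::vec& y,
                          double lambda, int max_iter, double tol) {
  const arma::uword n = Xa.n_rows, p = Xa.n_cols - 1;
  arma::vec beta(p + 1, arma::fill::zeros);
  arma::vec pen(p + 1, arma::fill::value(lambda));
  pen(0) = 0.0;  // intercept unpenalized

  auto objective = [&](const arma::vec& b) {
    arma::vec eta = Xa * b;
    // log(1+exp(eta)) computed stably
    arma::vec lse = arma::max(eta, arma::zeros<arma::vec>(n)) +
                    arma::log1p(arma::exp(-arma::abs(eta)));
    double obj = arma::accu(lse - y % eta);
    if (p > 0) obj += 0.5 * lambda * arma::dot(b.subvec(1, p), b.subvec(1, p));
    return obj;
  };

  double f_old = objective(beta);
  for (int it = 0; it < max_iter; ++it) {
    arma::vec eta = Xa * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
    arma::vec g = Xa.t() * (mu - y) + pen % beta;
    arma::mat H = Xa.t() * (Xa.each_col() % w);
    H.diag() += pen;
    arma::vec step;
    bool ok = arma::solve(step, H, g, arma::solve_opts::likely_sympd);
    if (!ok) {
      H.diag() += 1e-8;
      arma::solve(step, H, g);
    }
    // backtracking line search on the penalized deviance
    double t = 1.0;
    arma::vec beta_new;
    double f_new = f_old;
    for (int ls = 0; ls < 30; ++ls) {
      beta_new = beta - t * step;
      f_new = objective(beta_new);
      if (f_new <= f_old + 1e-12) break;
      t *= 0.5;
    }
    double delta = arma::abs(t * step).max();
    beta = beta_new;
    f_old = f_new;
    if (delta < tol) break;
  }
  return beta;
}

// [[Rcpp::export(name = ".ridge_logistic_fit_cpp")]]
NumericVector ridge_logistic_fit_cpp(const arma::mat& X,
                                     const arma::vec& y,
                                     double lambda,
                                     int max_iter = 50,
                                     double tol = 1e-9) {
  arma::mat Xa(X.n_rows, X.n_cols + 1);
  Xa.col(0).ones();
  if (X.n_cols > 0) Xa.cols(1, X.n_cols) = X;
  arma::vec beta = irls_fit(Xa, y, lambda, max_iter, tol);
  return NumericVector(beta.begin(), beta.end());
}

// Out-of-fold probabilities for one design matrix under a fold assignment.
// For each fold: training rows are mean-imputed (NaN entries), standardized
// with training statistics, the ridge-logistic model is fit, and the held
// fold is scored with the training-derived preprocessing parameters.
// [[Rcpp::export(name = ".ridge_logistic_oof_cpp")]]
NumericVector ridge_logistic_oof_cpp(const arma::mat& X,
                                     const arma::vec& y,
                                     const arma::ivec& folds,
                                     double lambda) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec out(n, arma::fill::zeros);
  arma::ivec uf = arma::unique(folds);
  for (arma::uword k = 0; k < uf.n_elem; ++k) {
    const int f = uf(k);
    arma::uvec tr = arma::find(folds != f);
    arma::uvec te = arma::find(folds == f);
    arma::mat Xtr = X.rows(tr);
    arma::mat Xte = X.rows(te);
    arma::rowvec mu(p), center(p), scl(p);
    for (arma::uword j = 0; j < p; ++j) {
      arma::vec col = Xtr.col(j);
      arma::uvec fin = arma::find_finite(col);
      double m = fin.n_elem ? arma::mean(col(fin)) : 0.0;
      mu(j) = m;
      for (arma::uword i = 0; i < col.n_elem; ++i)
        if (!arma::is_finite(col(i))) col(i) = m;
      Xtr.col(j) = col;
      center(j) = arma::mean(col);
      double s = col.n_elem > 1 ? arma::stddev(col) : 0.0;
      scl(j) = (std::isfinite(s) && s > 1e-12) ? s : 1.0;
    }
    Xtr.each_row() -= center;
    Xtr.each_row() /= scl;
    for (arma::uword j = 0; j < p; ++j)
      for (arma::uword i = 0; i < Xte.n_rows; ++i)
        if (!arma::is_finite(Xte(i, j))) Xte(i, j) = mu(j);
    Xte.each_row() -= center;
    Xte.each_row() /= scl;

    arma::mat Xa(Xtr.n_rows, p + 1);
    Xa.col(0).ones();
    if (p > 0) Xa.cols(1, p) = Xtr;
    arma::vec beta = irls_fit(Xa, y(tr), lambda, 50, 1e-9);
    arma::vec eta = beta(0) + Xte * beta.subvec(1, p);
    out(te) = 1.0 / (1.0 + arma::exp(-eta));
  }
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".ridge_logistic_predict_cpp")]]
NumericVector ridge_logistic_predict_cpp(const arma::mat& X,
                                         const arma::vec& beta) {
  arma::vec eta = beta(0) + X * beta.subvec(1, beta.n_elem - 1);
  arma::vec pr = 1.0 / (1.0 + arma::exp(-eta));
  return NumericVector(pr.begin(), pr.end());
}
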