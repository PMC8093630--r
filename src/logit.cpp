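// Iteratively reweighted least squares for unpenalized logistic
// regression, plus a fold loop returning out-of-fold predicted
// probabilities. Used in the exhaustive subset search where hundreds of
// thousands of small fits are needed; stats::glm serves as the oracle in
// the test suite. A small adaptive ridge keeps the normal equations
// solvable for collinear subsets, and the linear predictor is clamped so
// separable subsets converge to a finite, effectively 0/1 fit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double ETA_CLAMP = 15.0;

static arma::vec irls(const arma::mat& X, const arma::vec& y,
                      arma::vec beta, int maxit, double tol) {
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = arma::clamp(X * beta, -ETA_CLAMP, ETA_CLAMP);
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = p % (1.0 - p);
    arma::vec z = eta + (y - p) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    A.diag() += 1e-9 * (1.0 + A.diag().max());
    arma::vec bnew;
    if (!arma::solve(bnew, A, Xw.t() * z, arma::solve_opts::no_approx)) {
      A.diag() += 1e-4 * (1.0 + A.diag().max());
      bnew = arma::solve(A, Xw.t() * z);
    }
    double delta = arma::abs(bnew - beta).max();
    beta = bnew;
    if (delta < tol) break;
  }
  return beta;
}

// [[Rcpp::export]]
Rcpp::List logit_fit_cpp(const arma::mat& X, const arma::vec& y,
                         int maxit = 50, double tol = 1e-9) {
  arma::vec beta(X.n_cols, arma::fill::zeros);
  beta = irls(X, y, beta, maxit, tol);
  // observed-information standard errors at the solution
  arma::vec eta = arma::clamp(X * beta, -ETA_CLAMP, ETA_CLAMP);
  arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
  arma::vec w = p % (1.0 - p);
  arma::mat A = X.t() * (X.each_col() % w);
  A.diag() += 1e-9 * (1.0 + A.diag().max());
  arma::mat cov;
  if (!arma::inv_sympd(cov, A)) cov = arma::pinv(A);
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta,
      Rcpp::Named("se") = arma::sqrt(arma::abs(cov.diag())),
      Rcpp::Named("fitted") = p);
}

// Out-of-fold probabilities: foldid in 1..K; each fold's subjects are
// scored by the model fitted on the remaining subjects (warm-started at
// the full-data fit).
// [[Rcpp::export]]
arma::vec logit_cv_scores_cpp(const arma::mat& X, const arma::vec& y,
                              const arma::ivec& foldid,
                              int maxit = 30, double tol = 1e-8) {
  int n = X.n_rows;
  int K = foldid.max();
  arma::vec warm(X.n_cols, arma::fill::zeros);
  warm = irls(X, y, warm, maxit, tol);
  arma::vec scores(n, arma::fill::zeros);
  for (int k = 1; k <= K; ++k) {
    arma::uvec test = arma::find(foldid == k);
    arma::uvec train = arma::find(foldid != k);
    arma::vec beta = irls(X.rows(train), y.elem(train), warm, maxit, tol);
    arma::vec eta = arma::clamp(X.rows(test) * beta, -ETA_CLAMP, ETA_CLAMP);
    scores.elem(test) = 1.0 / (1.0 + arma::exp(-eta));
  }
  return scores;
}
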