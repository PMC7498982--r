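// Fast leave-one-out PLS1 prediction and permutation nulls.
//
// The permutation test re-runs the complete leave-one-out loop (fold-wise
// re-standardization included) for every permuted outcome vector, which at
// B = 10,000 means ~10^5 small PLS fits; this loop is the only part of the
// package hot enough to warrant compiled code. The algorithm mirrors
// pls1_core() in R/pls.R exactly: weights from the covariance with the
// outcome, X-deflation, coefficients B = W (P'W)^{-1} q. Sign conventions
// are irrelevant here because predictions are sign-invariant.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec pls1_beta(const mat& X, const vec& y, const int ncomp) {
  const uword p = X.n_cols;
  mat W(p, ncomp), P(p, ncomp);
  vec q(ncomp);
  mat Xk = X;
  for (int k = 0; k < ncomp; ++k) {
    vec w = Xk.t() * y;
    const double nw = norm(w);
    if (nw < 1e-12)
      Rcpp::stop("rank-deficient fold: covariance vanished at component %d",
                 k + 1);
    w /= nw;
    vec t = Xk * w;
    const double tt = dot(t, t);
    if (tt < 1e-12) Rcpp::stop("degenerate score in fold");
    vec pk = Xk.t() * t / tt;
    q(k) = dot(y, t) / tt;
    Xk -= t * pk.t();
    W.col(k) = w;
    P.col(k) = pk;
  }
  return W * solve(P.t() * W, q);
}

// one complete LOOCV pass: per fold, standardize train columns and outcome
// (n-1 SD) without the held-out row, fit PLS1, predict the held-out row
static vec loocv_pass(const mat& X, const vec& y, const int ncomp) {
  const uword n = X.n_rows, p = X.n_cols;
  vec pred(n);
  mat Xtr(n - 1, p);
  vec ytr(n - 1);
  for (uword i = 0; i < n; ++i) {
    uword r = 0;
    for (uword j = 0; j < n; ++j) {
      if (j == i) continue;
      Xtr.row(r) = X.row(j);
      ytr(r) = y(j);
      ++r;
    }
    rowvec mu = mean(Xtr, 0);
    rowvec sdx = stddev(Xtr, 0, 0);  // normalization by n-1
    const double muy = mean(ytr), sdy = stddev(ytr);
    if (sdx.min() < 1e-300 || sdy < 1e-300)
      Rcpp::stop("zero-variance column in fold %d", (int)i + 1);
    mat Xs = Xtr.each_row() - mu;
    Xs.each_row() /= sdx;
    vec ys = (ytr - muy) / sdy;
    vec beta = pls1_beta(Xs, ys, ncomp);
    rowvec xnew = (X.row(i) - mu) / sdx;
    pred(i) = dot(xnew, beta);
  }
  return pred;
}

// [[Rcpp::export]]
arma::vec cpp_loocv_predict(const arma::mat& X, const arma::vec& y,
                            const int ncomp) {
  if (X.n_rows != y.n_elem) Rcpp::stop("X and y sizes differ");
  if ((int)X.n_rows < ncomp + 3) Rcpp::stop("too few subjects for LOOCV");
  return loocv_pass(X, y, ncomp);
}

// predictions for each permuted outcome; perms is B x n, 1-based indices
// [[Rcpp::export]]
arma::mat cpp_permutation_predictions(const arma::mat& X, const arma::vec& y,
                                      const int ncomp,
                                      const arma::umat& perms) {
  const uword B = perms.n_rows, n = X.n_rows;
  if (perms.n_cols != n) Rcpp::stop("permutation matrix width must equal n");
  mat out(B, n);
  for (uword b = 0; b < B; ++b) {
    vec yp(n);
    for (uword j = 0; j < n; ++j) yp(j) = y(perms(b, j) - 1);
    out.row(b) = loocv_pass(X, yp, ncomp).t();
    if (b % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
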