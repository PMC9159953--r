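// Coordinate-descent lasso path with warm starts, plus the cross-validation
// and stability-selection inner loops that dominate the gene-wise runtime.
// Objective (glmnet convention, no intercept, no internal standardization):
//   (1/2n) ||y - X b||_2^2 + lambda ||b||_1
//
// The solver works on the covariance statistics S = X'X/n and q = X'y/n and
// maintains the gradient g = q - S b, so scanning a coordinate is O(1) and
// only actual coefficient changes cost O(p); inner loops iterate the active
// set with a full KKT sweep between rounds. CV folds reuse the full-data
// S and q by downdating the held-out rows.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double d) {
  if (x > d) return x - d;
  if (x < -d) return x + d;
  return 0.0;
}

// one sweep over the coordinates in `ord`; returns max |coef change|
static double cd_sweep(const mat& S, vec& g, vec& beta, double lam,
                       const uvec& ord) {
  double maxd = 0.0;                 // glmnet-style s_jj * delta^2 measure
  for (uword k = 0; k < ord.n_elem; ++k) {
    const uword j = ord[k];
    const double sjj = S(j, j);
    if (sjj <= 0) continue;
    const double bj = beta[j];
    const double bn = soft(g[j] + sjj * bj, lam) / sjj;
    if (bn != bj) {
      g += S.col(j) * (bj - bn);
      beta[j] = bn;
      const double d = sjj * (bn - bj) * (bn - bj);
      if (d > maxd) maxd = d;
    }
  }
  return maxd;
}

// warm-started path over a decreasing lambda sequence
static void cd_path_cov(const mat& S, const vec& q, const vec& lambda,
                        double tol, int max_iter, mat& B,
                        double ynorm2n = -1.0) {
  const uword p = S.n_cols, L = lambda.n_elem;
  vec beta(p, fill::zeros);
  vec g = q;                       // gradient at beta = 0
  const uvec all = regspace<uvec>(0, p - 1);
  for (uword l = 0; l < L; ++l) {
    const double lam = lambda[l];
    for (int it = 0; it < max_iter; ++it) {
      if (cd_sweep(S, g, beta, lam, all) < tol) break;
      // active-set inner loops until stable, then re-check all coordinates
      uvec act = find(beta != 0);
      for (int in = 0; in < max_iter; ++in)
        if (cd_sweep(S, g, beta, lam, act) < tol) break;
    }
    B.col(l) = beta;
    if (ynorm2n > 0) {
      // stop the path when the training deviance saturates (p > n tail);
      // remaining lambdas keep the saturated solution
      const double rss = ynorm2n - 2.0 * dot(beta, q) +
                         dot(beta, S * beta);
      if (rss < 1e-3 * ynorm2n) {
        for (uword l2 = l + 1; l2 < L; ++l2) B.col(l2) = beta;
        break;
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat lasso_path_cd(const arma::mat& X, const arma::vec& y,
                        const arma::vec& lambda, double tol = 1e-9,
                        int max_iter = 1000) {
  const double n = (double)X.n_rows;
  mat S = (X.t() * X) / n;
  vec q = (X.t() * y) / n;
  mat B(X.n_cols, lambda.n_elem, fill::zeros);
  cd_path_cov(S, q, lambda, tol, max_iter, B, dot(y, y) / n);
  return B;
}

// mean squared prediction error per lambda under leave-one-out CV
// [[Rcpp::export]]
arma::vec lasso_loo_mse(const arma::mat& X, const arma::vec& y,
                        const arma::vec& lambda, double tol = 1e-7,
                        int max_iter = 1000) {
  const uword n = X.n_rows, L = lambda.n_elem, p = X.n_cols;
  const mat Sn = X.t() * X;        // unnormalized
  const vec qn = X.t() * y;
  vec err(L, fill::zeros);
  mat B(p, L);
  for (uword i = 0; i < n; ++i) {
    const vec xi = X.row(i).t();
    const double ni = double(n - 1);
    mat S = (Sn - xi * xi.t()) / ni;
    vec q = (qn - y[i] * xi) / ni;
    B.zeros();
    const double yn2 = (dot(y, y) - y[i] * y[i]) / ni;
    cd_path_cov(S, q, lambda, tol, max_iter, B, yn2);
    for (uword l = 0; l < L; ++l) {
      const double e = y[i] - dot(xi, B.col(l));
      err[l] += e * e;
    }
  }
  return err / double(n);
}

// mean squared prediction error per lambda under k-fold CV; foldid is 1-based
// [[Rcpp::export]]
arma::vec lasso_kfold_mse(const arma::mat& X, const arma::vec& y,
                          const arma::vec& lambda,
                          const arma::uvec& foldid, double tol = 1e-7,
                          int max_iter = 1000) {
  const uword n = X.n_rows, L = lambda.n_elem, p = X.n_cols;
  const uword K = foldid.max();
  const mat Sn = X.t() * X;
  const vec qn = X.t() * y;
  vec err(L, fill::zeros);
  mat B(p, L);
  for (uword k = 1; k <= K; ++k) {
    const uvec test = find(foldid == k);
    if (test.n_elem == 0 || test.n_elem == n) continue;
    const mat Xt = X.rows(test);
    const vec yt = y(test);
    const double ni = double(n - test.n_elem);
    mat S = (Sn - Xt.t() * Xt) / ni;
    vec q = (qn - Xt.t() * yt) / ni;
    B.zeros();
    const double yn2 = (dot(y, y) - dot(yt, yt)) / ni;
    cd_path_cov(S, q, lambda, tol, max_iter, B, yn2);
    const mat pred = Xt * B;
    for (uword l = 0; l < L; ++l) {
      const vec e = yt - pred.col(l);
      err[l] += dot(e, e);
    }
  }
  return err / double(n);
}

// selection counts over stability rounds: column k of idx (1-based rows)
// is the subsample, lambda_k its perturbed penalty; each fit runs a short
// warm-started path ending at lambda_k
// [[Rcpp::export]]
arma::vec stability_counts_cd(const arma::mat& X, const arma::vec& y,
                              const arma::umat& idx,
                              const arma::vec& lambda_k, int path_len = 15,
                              double tol = 1e-7, int max_iter = 1000) {
  const uword p = X.n_cols, K = idx.n_cols;
  const double m = (double)idx.n_rows;
  vec counts(p, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    const uvec rows = idx.col(k) - 1;
    const mat Xs = X.rows(rows);
    const vec ys = y(rows);
    const mat S = (Xs.t() * Xs) / m;
    const vec q = (Xs.t() * ys) / m;
    double lmax = norm(q, "inf");
    const double ltar = lambda_k[k];
    if (lmax <= ltar) lmax = ltar * 20.0;
    vec path = exp(linspace<vec>(std::log(lmax), std::log(ltar), path_len));
    mat B(p, (uword)path_len, fill::zeros);
    cd_path_cov(S, q, path, tol, max_iter, B, dot(ys, ys) / m);
    counts += conv_to<vec>::from(B.col(path_len - 1) != 0);
  }
  return counts;
}
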