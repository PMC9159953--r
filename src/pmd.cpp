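// Penalized rank-1 matrix decomposition inner loop: alternating scaled
// soft-thresholding with a bisection search for the l1 threshold.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// project x onto {u : ||u||_2 = 1, ||u||_1 <= c}; sparsest-vertex fallback
// when ties at the maximum make the constraint infeasible
static vec l1_unit_cpp(const vec& x, double c) {
  if (!any(x != 0)) return x;
  vec u = x / norm(x, 2);
  if (norm(u, 1) <= c) return u;
  double lo = 0.0, hi = max(abs(x));
  for (int it = 0; it < 60; ++it) {
    const double mid = 0.5 * (lo + hi);
    vec su = sign(x) % clamp(abs(x) - mid, 0.0, datum::inf);
    const double nrm = norm(su, 2);
    if (nrm == 0 || norm(su, 1) / nrm > c) lo = mid; else hi = mid;
  }
  vec su = sign(x) % clamp(abs(x) - hi, 0.0, datum::inf);
  const double nrm = norm(su, 2);
  if (nrm == 0) {
    vec out(x.n_elem, fill::zeros);
    const uword j = index_max(abs(x));
    out[j] = (x[j] > 0) ? 1.0 : -1.0;
    return out;
  }
  return su / nrm;
}

// [[Rcpp::export]]
Rcpp::List pmd_rank1_cpp(const arma::mat& C, double c1, double c2,
                         const arma::vec& v0, double tol = 1e-6,
                         int max_iter = 100) {
  vec v = v0;
  vec u(C.n_rows, fill::zeros);
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    vec u_new = l1_unit_cpp(C * v, c1);
    vec v_new = l1_unit_cpp(C.t() * u_new, c2);
    const double delta = std::max(abs(u_new - u).max(),
                                  abs(v_new - v).max());
    u = u_new; v = v_new;
    if (delta < tol) { converged = true; break; }
  }
  const double d = dot(u, C * v);
  return Rcpp::List::create(Rcpp::Named("u") = u, Rcpp::Named("v") = v,
                            Rcpp::Named("d") = d,
                            Rcpp::Named("iters") = std::min(it, max_iter),
                            Rcpp::Named("converged") = converged);
}
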