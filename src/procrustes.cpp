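// Symmetric-Procrustes permutation statistics. With both configurations
// centred and scaled to unit sum of squares, the Procrustes correlation is
// the sum of singular values of X'Y and m2 = 1 - (sum sv)^2. Row permutation
// leaves centring and scale intact, so the permutation loop only needs a
// small svd per draw.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::vec procrustes_perm_stats(const arma::mat& X, const arma::mat& Y,
                                const arma::umat& perms) {
  const uword P = perms.n_rows;
  vec stats(P);
  for (uword p = 0; p < P; ++p) {
    const uvec ord = perms.row(p).t() - 1;      // 1-based from R
    vec sv = svd(X.t() * Y.rows(ord));
    stats[p] = accu(sv);
  }
  return stats;
}
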