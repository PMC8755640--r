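// Orthogonal matching pursuit core. Single implementation shared by the
// user-facing sparse coder and the KSVD inner loop.
//
// Contract (mirrors the R-level documentation):
//  - the signal is unit-normalized before pursuit; eps is an absolute
//    residual threshold on the normalized signal; returned coefficients
//    are rescaled back to the input scale;
//  - atom selection by maximum absolute correlation, ties -> lowest index;
//  - full least-squares refit of the selected coefficients each step,
//    minimum-norm (pseudoinverse) solution when the selected atoms are
//    collinear;
//  - stop at T atoms, residual <= eps, or residual orthogonal to all atoms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec omp_one(const mat& D, const vec& y, const int T, const double eps) {
  const uword n = D.n_cols;
  vec x(n, fill::zeros);
  const double ynorm = norm(y, 2);
  if (ynorm == 0.0) return x;
  const vec u = y / ynorm;

  uvec support(static_cast<uword>(T));
  uword nsel = 0;
  vec r = u;
  double rnorm = 1.0;
  vec coef;

  while (nsel < static_cast<uword>(T) && rnorm > eps) {
    vec corr = abs(D.t() * r);
    for (uword i = 0; i < nsel; ++i) corr(support(i)) = -datum::inf;
    const uword best = corr.index_max();  // first (lowest-index) maximum
    if (!std::isfinite(corr(best)) || corr(best) <= 1e-14) break;
    support(nsel++) = best;

    const mat Ds = D.cols(support.head(nsel));
    bool ok = solve(coef, Ds, u, solve_opts::no_approx + solve_opts::fast);
    if (!ok || !coef.is_finite()) coef = pinv(Ds, 1e-10) * u;  // minimum-norm
    r = u - Ds * coef;
    rnorm = norm(r, 2);
  }
  for (uword i = 0; i < nsel; ++i) x(support(i)) = coef(i) * ynorm;
  return x;
}

// [[Rcpp::export(name = ".omp_code_cpp")]]
arma::vec omp_code_cpp(const arma::mat& D, const arma::vec& y,
                       const int T, const double eps) {
  return omp_one(D, y, T, eps);
}

// [[Rcpp::export(name = ".omp_code_matrix_cpp")]]
arma::mat omp_code_matrix_cpp(const arma::mat& D, const arma::mat& Y,
                              const int T, const double eps) {
  mat X(D.n_cols, Y.n_cols, fill::zeros);
  for (uword i = 0; i < Y.n_cols; ++i) {
    X.col(i) = omp_one(D, Y.col(i), T, eps);
  }
  return X;
}
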