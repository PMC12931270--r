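// Core SparCC kernel: basis variances from log-ratio variances under the
// sparsity approximation, with iterative exclusion of strongly correlated
// pairs. M = (D-2) I + J has a closed-form inverse and every pair
// exclusion is a rank-1 downdate (u = e_i + e_j), so M^-1 is maintained by
// Sherman-Morrison instead of repeated solves.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List basisCorrelationsCpp(const arma::mat& T,
                                double exclusionThreshold,
                                int maxExclusions,
                                double varianceFloor) {
  const uword D = T.n_rows;
  mat Minv(D, D);
  Minv.fill(-1.0 / ((D - 2.0) * (2.0 * D - 2.0)));
  Minv.diag() += 1.0 / (D - 2.0);
  vec tvec = sum(T, 1);
  umat excluded(D, D, fill::zeros);
  bool clamped = false;
  mat rho(D, D, fill::eye);

  for (int round = 0; round <= maxExclusions; ++round) {
    vec omega = Minv * tvec;
    if (!omega.is_finite()) break;  // degenerated: keep last estimate
    if (omega.min() < varianceFloor) {
      clamped = true;
      omega.elem(find(omega < varianceFloor)).fill(varianceFloor);
    }
    vec so = sqrt(omega);
    for (uword j = 0; j < D; ++j) {
      for (uword i = 0; i < D; ++i) {
        double v = (omega(i) + omega(j) - T(i, j)) / (2.0 * so(i) * so(j));
        if (v > 1.0) v = 1.0;
        if (v < -1.0) v = -1.0;
        rho(i, j) = v;
      }
    }
    rho.diag().ones();
    if (round == maxExclusions) break;

    double mx = 0.0;
    uword bi = 0, bj = 0;
    for (uword j = 1; j < D; ++j)
      for (uword i = 0; i < j; ++i)
        if (!excluded(i, j) && std::abs(rho(i, j)) > mx) {
          mx = std::abs(rho(i, j));
          bi = i; bj = j;
        }
    if (mx <= exclusionThreshold) break;
    excluded(bi, bj) = excluded(bj, bi) = 1;
    vec u = Minv.col(bi) + Minv.col(bj);
    double denom = 1.0 - (u(bi) + u(bj));
    if (std::abs(denom) < 1e-12) break;  // downdate would be singular
    Minv += (u * u.t()) / denom;
    tvec(bi) -= T(bi, bj);
    tvec(bj) -= T(bi, bj);
  }
  return Rcpp::List::create(Rcpp::Named("rho") = rho,
                            Rcpp::Named("clamped") = clamped);
}
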