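// Coordinate-descent kernels for the alternating Newton solver.
// Both kernels make `sweeps` passes over the supplied active set in the
// given (deterministic) order and maintain the product caches in place:
//   Theta pass:  W = S_in * Theta
//   Lambda pass: U = Delta * Sigma
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double c, double thr) {
  if (c > thr) return c - thr;
  if (c < -thr) return c + thr;
  return 0.0;  // ties at the boundary resolve to exact zero
}

// Lasso subproblem for Theta given Lambda:
//   argmin tr(2 S_cross' Theta + Sigma Theta' S_in Theta) + lam ||Theta||_1
// act: m x 2 zero-based (row, col) indices.
// [[Rcpp::export]]
Rcpp::List cd_theta_cpp(arma::mat Theta, arma::mat W,
                        const arma::mat& S_in, const arma::mat& S_cross,
                        const arma::mat& Sigma, double lam,
                        const arma::imat& act, int sweeps) {
  int skipped = 0;
  for (int s = 0; s < sweeps; ++s) {
    for (uword k = 0; k < act.n_rows; ++k) {
      const uword i = (uword)act(k, 0), j = (uword)act(k, 1);
      const double h = 2.0 * S_in(i, i) * Sigma(j, j);
      if (h <= 0.0) { if (s == 0) ++skipped; continue; }  // non-informative input
      const double g = 2.0 * S_cross(i, j) + 2.0 * dot(W.row(i), Sigma.col(j));
      const double tnew = soft(Theta(i, j) - g / h, lam / h);
      const double d = tnew - Theta(i, j);
      if (d != 0.0) {
        Theta(i, j) = tnew;
        W.col(j) += d * S_in.col(i);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("skipped") = skipped);
}

// Newton-direction Lasso subproblem for Lambda:
//   argmin vec(G)'vec(D) + 1/2 vec(D)' (Sigma x M) vec(D)
//          + lam ||Lambda + D||_1(offdiag)
// with M = Sigma + 2 Psi; G = S_out - Sigma - Psi; D symmetric.
// act: m x 2 zero-based pairs with i <= j (diagonals included, unpenalized).
// [[Rcpp::export]]
Rcpp::List cd_lambda_cpp(arma::mat Delta, arma::mat U,
                         const arma::mat& G, const arma::mat& Sigma,
                         const arma::mat& M, const arma::mat& Lambda,
                         double lam, const arma::imat& act, int sweeps) {
  for (int s = 0; s < sweeps; ++s) {
    for (uword k = 0; k < act.n_rows; ++k) {
      const uword i = (uword)act(k, 0), j = (uword)act(k, 1);
      if (i == j) {
        const double h = M(i, i) * Sigma(i, i);
        if (h <= 0.0) continue;
        const double a = G(i, i) + dot(M.col(i), U.col(i));
        const double mu = -a / h;
        if (mu != 0.0) {
          Delta(i, i) += mu;
          U.row(i) += mu * Sigma.row(i);
        }
      } else {
        const double h = 2.0 * M(i, j) * Sigma(i, j) +
          M(j, j) * Sigma(i, i) + M(i, i) * Sigma(j, j);
        if (h <= 0.0) continue;
        const double a = 2.0 * G(i, j) +
          dot(M.col(i), U.col(j)) + dot(M.col(j), U.col(i));
        const double c = Lambda(i, j) + Delta(i, j);
        const double mu = soft(c - a / h, 2.0 * lam / h) - c;
        if (mu != 0.0) {
          Delta(i, j) += mu; Delta(j, i) += mu;
          U.row(i) += mu * Sigma.row(j);
          U.row(j) += mu * Sigma.row(i);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Delta") = Delta,
                            Rcpp::Named("U") = U);
}
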