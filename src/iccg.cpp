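// Incomplete-Cholesky preconditioned conjugate gradients for SPD systems.
// The incomplete factor L keeps the sparsity pattern of A: l_ij is computed
// by the complete Cholesky formula wherever a_ij != 0 and set to zero
// otherwise, so A = L L^T + R with R the dropped residual.  On breakdown
// (non-positive pivot) the factorization restarts with a diagonal shift.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using Rcpp::List;
using Rcpp::Named;

// returns lower-triangular L with the pattern of A, and the shift used
static bool ic0_dense(const arma::mat &A, arma::mat &L, double shift) {
  const int n = A.n_rows;
  L.zeros(n, n);
  for (int j = 0; j < n; ++j) {
    double d = A(j, j) + shift * A(j, j);
    for (int k = 0; k < j; ++k) d -= L(j, k) * L(j, k);
    if (d <= 0.0) return false;
    L(j, j) = std::sqrt(d);
    for (int i = j + 1; i < n; ++i) {
      if (A(i, j) == 0.0) continue;      // drop: keep the pattern of A
      double s = A(i, j);
      for (int k = 0; k < j; ++k) s -= L(i, k) * L(j, k);
      L(i, j) = s / L(j, j);
    }
  }
  return true;
}

// [[Rcpp::export(name = ".iccg_solve_cpp")]]
List iccg_solve_cpp(const arma::mat &A, const arma::vec &b,
                    double tol = 1e-10, int maxit = 0,
                    bool precondition = true) {
  const int n = A.n_rows;
  if (maxit <= 0) maxit = 10 * n;

  arma::mat L;
  double shift_used = 0.0;
  if (precondition) {
    bool ok = ic0_dense(A, L, 0.0);
    double shift = 1e-3;
    while (!ok && shift < 1e3) {
      ok = ic0_dense(A, L, shift);
      if (ok) shift_used = shift;
      shift *= 10.0;
    }
    if (!ok) Rcpp::stop("incomplete Cholesky broke down even with diagonal shifts: is A symmetric positive definite?");
  }

  arma::vec x(n, arma::fill::zeros);
  arma::vec r = b;
  double bn = arma::norm(b);
  if (bn == 0.0)
    return List::create(Named("x") = x, Named("iterations") = 0,
                        Named("residual") = 0.0, Named("shift") = shift_used);

  auto apply_prec = [&](const arma::vec &v) -> arma::vec {
    if (!precondition) return v;
    arma::vec y = arma::solve(arma::trimatl(L), v);
    return arma::solve(arma::trimatu(L.t()), y);
  };

  arma::vec z = apply_prec(r);
  arma::vec p = z;
  double rz = arma::dot(r, z);
  int it = 0;
  double relres = arma::norm(r) / bn;
  while (relres > tol && it < maxit) {
    arma::vec Ap = A * p;
    double alpha = rz / arma::dot(p, Ap);
    x += alpha * p;
    r -= alpha * Ap;
    relres = arma::norm(r) / bn;
    ++it;
    if (relres <= tol) break;
    z = apply_prec(r);
    double rz_new = arma::dot(r, z);
    p = z + (rz_new / rz) * p;
    rz = rz_new;
  }
  if (relres > tol)
    Rcpp::stop("conjugate gradients did not converge in %d iterations (relative residual %g)",
               it, relres);
  return List::create(Named("x") = x, Named("iterations") = it,
                      Named("residual") = relres, Named("shift") = shift_used);
}
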