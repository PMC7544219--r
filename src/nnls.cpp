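// Lawson-Hanson active-set non-negative least squares.
// Solves min ||A x - b||_2 subject to x >= 0. Used for the Tikhonov
// inversion on the stacked system [K; alpha * L2]; the non-negativity of
// the distance distribution is a hard constraint, not a post-hoc clip.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List nnls_solve(const arma::mat& A, const arma::vec& b,
                      const double tol_rel = 1e-10,
                      const int max_iter_mult = 10) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * (b - A * x);
  const double tol = tol_rel * std::max(1.0, norm(A.t() * b, "inf"));
  const int max_outer = max_iter_mult * static_cast<int>(n);
  int outer = 0;

  while (outer++ < max_outer) {
    // most violated KKT multiplier among the active (zero) set
    double wmax = -datum::inf;
    sword jmax = -1;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (jmax < 0 || wmax <= tol) break;
    passive[jmax] = true;

    // inner loop: solve unconstrained on the passive set, backtrack if
    // any passive coordinate goes nonpositive
    for (;;) {
      uvec P(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      const bool ok = solve(z, A.cols(P), b,
                            solve_opts::fast + solve_opts::no_approx);
      if (!ok) {
        vec z2 = pinv(A.cols(P)) * b;
        z = z2;
      }
      if (z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k) {
        if (z(k) <= 0) {
          const double xi = x(P(k));
          const double a = xi / (xi - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (uword k = 0; k < np; ++k) {
        const double xi = x(P(k));
        x(P(k)) = xi + alpha * (z(k) - xi);
      }
      for (uword k = 0; k < np; ++k) {
        if (x(P(k)) <= 1e-14) { passive[P(k)] = false; x(P(k)) = 0.0; }
      }
    }
    w = A.t() * (b - A * x);
  }

  return Rcpp::List::create(
      Rcpp::Named("x") = x,
      Rcpp::Named("converged") = outer < max_outer);
}
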