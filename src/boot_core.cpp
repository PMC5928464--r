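// Cluster-bootstrap core for the long-term direct-effect test.
//
// Each resample re-runs the full three-step procedure: (1) linear SCMM of
// the outcome on all exposure and prior-outcome lags, (2) predicted
// outcomes with the current exposure forced to the reference value,
// (3) pooled logistic regression of the lagged exposure on the deeper
// history plus those predictions. Only the last coefficient (on the
// predicted outcome) is retained per resample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// logistic IRLS; returns true on convergence, beta passed by reference
static bool irls_logistic(const mat& X, const vec& y, vec& beta,
                          const int maxit, const double tol) {
  const uword p = X.n_cols;
  beta.zeros(p);
  for (int it = 0; it < maxit; ++it) {
    vec eta = clamp(X * beta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w = clamp(w, 1e-10, 0.25);
    mat Xw = X.each_col() % w;
    mat H = X.t() * Xw;
    vec g = X.t() * (y - mu);
    vec step;
    if (!solve(step, H, g, solve_opts::no_approx)) return false;
    beta += step;
    if (!beta.is_finite()) return false;
    if (abs(step).max() < tol) return true;
  }
  return false;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix boot_direct_effect_cpp(const arma::mat& M1,
                                           const arma::vec& y1,
                                           const int x0_col,
                                           const double ref,
                                           const arma::mat& M3,
                                           const arma::vec& y3,
                                           const arma::imat& idx,
                                           const int T) {
  const uword n = idx.n_rows;      // subjects per resample
  const uword B = idx.n_cols;
  const uword p1 = M1.n_cols;
  const uword p3 = M3.n_cols + 1;  // + predicted-outcome column
  const uword T1 = (uword)T;       // step-1 rows per subject
  const uword T3 = T1 - 1;         // step-3 rows per subject (visits 2..T)

  mat M1b(n * T1, p1), M3b(n * T3, p3);
  vec y1b(n * T1), y3b(n * T3);
  Rcpp::NumericMatrix out(B, 2);   // (delta, ok)

  for (uword b = 0; b < B; ++b) {
    for (uword i = 0; i < n; ++i) {
      const uword s = (uword)(idx(i, b) - 1);   // 1-based subject index
      M1b.rows(i * T1, i * T1 + T1 - 1) = M1.rows(s * T1, s * T1 + T1 - 1);
      y1b.subvec(i * T1, i * T1 + T1 - 1) = y1.subvec(s * T1, s * T1 + T1 - 1);
      M3b.submat(i * T3, 0, i * T3 + T3 - 1, p3 - 2) =
        M3.rows(s * T3, s * T3 + T3 - 1);
      y3b.subvec(i * T3, i * T3 + T3 - 1) = y3.subvec(s * T3, s * T3 + T3 - 1);
    }

    bool ok = true;
    vec beta1;
    {
      mat A = M1b.t() * M1b;
      vec rhs = M1b.t() * y1b;
      ok = solve(beta1, A, rhs, solve_opts::no_approx);
    }
    double delta = NA_REAL;
    if (ok) {
      // predicted outcome with the current exposure at the reference value
      vec yhat = M1b * beta1 -
        beta1((uword)x0_col) * (M1b.col((uword)x0_col) - ref);
      for (uword i = 0; i < n; ++i) {
        // visits 2..T of subject block i are step-1 rows 1..T-1
        M3b.submat(i * T3, p3 - 1, i * T3 + T3 - 1, p3 - 1) =
          yhat.subvec(i * T1 + 1, i * T1 + T1 - 1);
      }
      vec beta3;
      ok = irls_logistic(M3b, y3b, beta3, 25, 1e-8);
      if (ok) delta = beta3(p3 - 1);
    }
    out(b, 0) = delta;
    out(b, 1) = ok ? 1.0 : 0.0;
  }
  return out;
}
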