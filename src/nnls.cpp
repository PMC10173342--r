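#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min_x >= 0  0.5 x'Gx - x'h for one right-hand side by the
// Lawson-Hanson active-set method expressed on the normal equations
// (the "fast NNLS" formulation used throughout chemometric ALS code).
// G must be symmetric positive semi-definite; a tiny ridge is added
// on the fly if a passive-set subsystem is numerically singular.
static vec nnls_one(const mat& G, const vec& h, double tol) {
  const uword n = G.n_rows;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = h; // gradient of the dual: h - G x, x = 0 initially

  const uword max_outer = 30 * n + 30;
  for (uword outer = 0; outer < max_outer; ++outer) {
    // pick the most violated KKT multiplier among active constraints
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (int)j; }
    }
    if (t < 0) break; // KKT satisfied
    passive[t] = true;

    for (uword inner = 0; inner < max_outer; ++inner) {
      uvec P(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      if (np == 0) { x.zeros(); break; }
      P.resize(np);

      mat Gpp = G.submat(P, P);
      vec hp = h.elem(P);
      vec s;
      if (!solve(s, Gpp, hp, solve_opts::no_approx)) {
        mat Gr = Gpp + eye(np, np) * (trace(Gpp) / np * 1e-12 + datum::eps);
        s = solve(Gr, hp);
      }

      if (s.min() > 0) {
        x.zeros();
        x.elem(P) = s;
        break;
      }
      // step toward s until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k) {
        if (s(k) <= 0) {
          double xk = x(P(k));
          double a = xk / (xk - s(k));
          if (a < alpha) alpha = a;
        }
      }
      for (uword k = 0; k < np; ++k) {
        double xnew = x(P(k)) + alpha * (s(k) - x(P(k)));
        x(P(k)) = (xnew < tol) ? 0.0 : xnew;
      }
      for (uword k = 0; k < np; ++k) {
        if (x(P(k)) <= 0) { passive[P(k)] = false; x(P(k)) = 0.0; }
      }
    }
    w = h - G * x;
  }
  return x;
}

//' @title Batched non-negative least squares on the normal equations
//' @description For each column \code{h} of \code{H}, solves
//'   \code{min_{x >= 0} 0.5 x'Gx - x'h}, i.e. the NNLS problem
//'   \code{min ||Z b - y||} expressed through \code{G = Z'Z},
//'   \code{h = Z'y}. Internal workhorse of the constrained ALS updates.
//' @param G symmetric positive semi-definite cross-product matrix (F x F)
//' @param H matrix of right-hand sides, one problem per column (F x n)
//' @return matrix of non-negative solutions, one per column (F x n)
//' @keywords internal
// [[Rcpp::export]]
arma::mat nnls_cross(const arma::mat& G, const arma::mat& H) {
  if (G.n_rows != G.n_cols) Rcpp::stop("G must be square");
  if (H.n_rows != G.n_rows) Rcpp::stop("nrow(H) must equal nrow(G)");
  double tol = 10.0 * datum::eps * norm(G, "inf") * G.n_rows;
  if (tol <= 0) tol = datum::eps;
  mat X(G.n_rows, H.n_cols);
  for (uword j = 0; j < H.n_cols; ++j) {
    X.col(j) = nnls_one(G, H.col(j), tol);
  }
  return X;
}
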