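# Independent oracles used by both the unit and the acceptance suites.

nnls_objective <- function(X, y, b) sum((X %*% b - y)^2)

# coarse sweep of the non-negative orthant + box-constrained refinement
nnls_grid_oracle <- function(X, y) {
  p <- ncol(X)
  ols <- qr.solve(crossprod(X), crossprod(X, y))
  hi <- max(1, 2 * max(abs(ols)))
  axes <- replicate(p, seq(0, hi, length.out = 21), simplify = FALSE)
  grid <- as.matrix(expand.grid(axes))
  vals <- colSums((tcrossprod(X, grid) - as.vector(y))^2)
  start <- grid[which.min(vals), ]
  optim(start, function(b) nnls_objective(X, y, b),
        method = "L-BFGS-B", lower = rep(0, p),
        control = list(factr = 1e1, maxit = 500))
}

# minimum-norm least squares via SVD (handles rank deficiency the same
# way a Moore-Penrose solve does)
lstsq_minnorm <- function(M, y) {
  s <- svd(M)
  tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  drop(s$v[, keep, drop = FALSE] %*%
         (crossprod(s$u[, keep, drop = FALSE], y) / s$d[keep]))
}

# brute-force Tucker core of a fitted model through the explicit
# Kronecker design (vec(X) = (C (x) B (x) A) vec(G))
core_oracle <- function(model, cube) {
  F <- model$F
  Kd <- kronecker(model$ex_loadings,
                  kronecker(model$em_loadings, model$scores))
  array(lstsq_minnorm(Kd, as.vector(cube$data)), c(F, F, F))
}

# studentized range upper tail by direct numerical integration,
# independent of stats::ptukey
prange_oracle <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1)
      k * integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
    }, numeric(1))
  }
  fs <- function(s) 2 * (df / 2)^(df / 2) / gamma(df / 2) *
    s^(df - 1) * exp(-df * s^2 / 2)  # density of sqrt(chi^2_df / df)
  cdf <- integrate(function(s) fs(s) * inner(s), 0, Inf,
                   rel.tol = 1e-10)$value
  1 - cdf
}
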