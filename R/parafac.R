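## Trilinear (PARAFAC) decomposition of EEM cubes by alternating least
## squares with exact non-negative least-squares mode updates.

khatri_rao <- function(A, B) {
  # column-wise Kronecker product; B index runs fastest within a column
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (f in seq_len(ncol(A))) out[, f] <- kronecker(A[, f], B[, f])
  out
}

unfold_cube <- function(x) {
  d <- dim(x)
  list(m1 = matrix(x, d[1], d[2] * d[3]),
       m2 = matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3]),
       m3 = matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2]))
}

ttm <- function(arr, M, mode) {
  # tensor-times-matrix along one mode
  d <- dim(arr)
  perm <- c(mode, setdiff(seq_along(d), mode))
  mat <- matrix(aperm(arr, perm), d[mode])
  res <- M %*% mat
  out <- array(res, c(nrow(M), d[perm[-1]]))
  aperm(out, order(perm))
}

pinv <- function(M, tol = NULL) {
  s <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Exact non-negative least squares
#'
#' Solves \code{min ||design \%*\% b - y||} subject to \code{b >= 0} for
#' each column \code{y} of \code{targets}, by an active-set method on the
#' normal equations (exact at convergence, not a clipped unconstrained
#' solution). This is the subproblem solved for every mode update of the
#' constrained alternating least squares.
#'
#' @param design numeric matrix (n x p)
#' @param targets numeric vector or matrix (n x m) of right-hand sides
#' @param ridge if \code{TRUE}, a tiny ridge is added when the design is
#'   rank-deficient instead of failing
#' @param mode_name label used in error messages (the ALS mode being
#'   updated)
#' @return non-negative coefficient matrix (p x m), or a vector if
#'   \code{targets} is a vector
#' @examples
#' nnls_solve(diag(2), c(-1, 2))  # c(0, 2)
#' @export
nnls_solve <- function(design, targets, ridge = FALSE, mode_name = NULL) {
  design <- as.matrix(design)
  vec_in <- is.null(dim(targets))
  targets <- as.matrix(targets)
  stopifnot(nrow(design) == nrow(targets))
  G <- crossprod(design)
  if (qr(design)$rank < ncol(design)) {
    if (!ridge)
      stop("rank-deficient design",
           if (!is.null(mode_name)) paste0(" for mode '", mode_name, "'"),
           " (enable ridge fallback to proceed)")
    G <- G + diag(mean(diag(G)) * 1e-10 + .Machine$double.eps,
                  ncol(design))
  }
  out <- nnls_cross(G, crossprod(design, targets))
  if (vec_in) drop(out) else out
}

canonicalize_cp <- function(A, B, C) {
  F <- ncol(A)
  for (f in seq_len(F)) {
    nb <- sqrt(sum(B[, f]^2)); nc <- sqrt(sum(C[, f]^2))
    if (nb > 0) B[, f] <- B[, f] / nb
    if (nc > 0) C[, f] <- C[, f] / nc
    A[, f] <- A[, f] * nb * nc
  }
  energy <- colSums(A^2)
  # order by decreasing score energy; break exact ties lexicographically
  # on the emission loading so the output is fully deterministic
  tie_key <- apply(B, 2, function(v) paste(format(v, digits = 15),
                                           collapse = ","))
  ord <- order(-energy, tie_key)
  list(A = A[, ord, drop = FALSE], B = B[, ord, drop = FALSE],
       C = C[, ord, drop = FALSE])
}

als_run <- function(unf, dims, A, B, C, ssX, tol, max_iter) {
  sse_trace <- numeric(0)
  sse_prev <- Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    AtA <- crossprod(A); BtB <- crossprod(B); CtC <- crossprod(C)
    A <- t(nnls_cross(CtC * BtB, t(unf$m1 %*% khatri_rao(C, B))))
    AtA <- crossprod(A)
    B <- t(nnls_cross(CtC * AtA, t(unf$m2 %*% khatri_rao(C, A))))
    BtB <- crossprod(B)
    H3 <- unf$m3 %*% khatri_rao(B, A)
    C <- t(nnls_cross(BtB * AtA, t(H3)))
    sse <- ssX - 2 * sum(C * H3) + sum(crossprod(C) * (BtB * AtA))
    sse <- max(sse, 0)
    sse_trace <- c(sse_trace, sse)
    if (is.finite(sse_prev) &&
        abs(sse_prev - sse) <= tol * max(sse_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    sse_prev <- sse
  }
  list(A = A, B = B, C = C, sse = sse_trace[length(sse_trace)],
       sse_trace = sse_trace, n_iterations = it, converged = converged)
}

svd_init <- function(unf, dims, F) {
  lead <- function(M, n) {
    u <- svd(M, nu = min(n, min(dim(M))), nv = 0)$u
    u <- abs(u)
    if (ncol(u) < n)  # rank/size shortfall: pad deterministically
      u <- cbind(u, matrix(1 / sqrt(nrow(u)), nrow(u), n - ncol(u)))
    u
  }
  list(A = lead(unf$m1, F), B = lead(unf$m2, F), C = lead(unf$m3, F))
}

#' Fit a non-negative PARAFAC model to an EEM cube
#'
#' Decomposes a complete (preprocessed) sample x emission x excitation
#' cube into \code{F} trilinear components
#' \eqn{\hat x_{ijk} = \sum_f a_{if} b_{jf} c_{kf}} with all factor
#' entries constrained non-negative. Each mode update solves its exact
#' NNLS subproblem, so the residual sum of squares is non-increasing over
#' iterations. Among \code{n_starts} runs (one SVD-informed start plus
#' seeded random non-negative starts) the lowest-SSE solution is returned
#' in canonical form: unit-norm loading columns, all magnitude in the
#' scores, components ordered by decreasing score energy.
#'
#' @param cube a preprocessed \code{eem_cube} (no missing cells)
#' @param F number of components (>= 1)
#' @param n_starts number of initializations (default 10)
#' @param seed integer seed making the random starts reproducible
#' @param tol relative change in SSE at which iteration stops
#' @param max_iter maximum ALS iterations for the refined solution
#' @param start_iter iteration cap for the exploratory multi-start
#'   phase: every start runs at most this many iterations, then only the
#'   lowest-SSE candidate is iterated to convergence (the usual
#'   multi-start economy for ALS; set \code{start_iter = max_iter} to
#'   run every start to convergence)
#' @return an object of class \code{parafac_model}: list with \code{F},
#'   \code{scores} (I x F), \code{em_loadings} (J x F), \code{ex_loadings}
#'   (K x F) and \code{diagnostics} (explained variance \%, SSE trace,
#'   iteration count, convergence flag, core consistency \%)
#' @seealso \code{\link{explained_variance}}, \code{\link{corcondia}},
#'   \code{\link{match_components}}
#' @export
fit_parafac <- function(cube, F, n_starts = 10, seed = NULL,
                        tol = 1e-8, max_iter = 2000, start_iter = 150) {
  stopifnot(inherits(cube, "eem_cube"), F >= 1, n_starts >= 1)
  x <- cube$data
  if (anyNA(x))
    stop("cube contains unmeasured cells; run preprocess_cube() first")
  if (!all(is.finite(x))) stop("cube contains non-finite intensities")
  dims <- dim(x)
  unf <- unfold_cube(x)
  ssX <- sum(x^2)

  starts <- vector("list", n_starts)
  starts[[1]] <- svd_init(unf, dims, F)
  if (n_starts > 1) {
    starts[2:n_starts] <- with_seed(seed, lapply(2:n_starts, function(s) {
      list(A = matrix(stats::runif(dims[1] * F), dims[1], F),
           B = matrix(stats::runif(dims[2] * F), dims[2], F),
           C = matrix(stats::runif(dims[3] * F), dims[3], F))
    }))
  }

  explore_iter <- min(start_iter, max_iter)
  best <- NULL
  for (s in seq_len(n_starts)) {
    run <- als_run(unf, dims, starts[[s]]$A, starts[[s]]$B, starts[[s]]$C,
                   ssX, tol, if (n_starts > 1) explore_iter else max_iter)
    if (is.null(best) || run$sse < best$sse) {
      best <- run
      best$start <- s
    }
  }
  if (n_starts > 1 && !best$converged && max_iter > explore_iter) {
    cont <- als_run(unf, dims, best$A, best$B, best$C, ssX, tol,
                    max_iter - explore_iter)
    cont$sse_trace <- c(best$sse_trace, cont$sse_trace)
    cont$n_iterations <- best$n_iterations + cont$n_iterations
    cont$start <- best$start
    best <- cont
  }
  if (!best$converged)
    warning("ALS did not converge within ", max_iter,
            " iterations (best start ", best$start, ")")

  cf <- canonicalize_cp(best$A, best$B, best$C)
  model <- structure(
    list(F = as.integer(F),
         scores = cf$A, em_loadings = cf$B, ex_loadings = cf$C,
         grid = cube$grid,
         diagnostics = list(
           explained_variance_pct = 100 * (1 - best$sse / ssX),
           sse = best$sse,
           sse_trace = best$sse_trace,
           n_iterations = best$n_iterations,
           converged = best$converged,
           n_starts = n_starts, best_start = best$start, seed = seed,
           core_consistency_pct = NA_real_)),
    class = "parafac_model")
  model$diagnostics$core_consistency_pct <- corcondia(model, cube)
  model
}

#' @export
print.parafac_model <- function(x, ...) {
  d <- x$diagnostics
  cat("Non-negative PARAFAC model with", x$F, "components\n")
  cat(sprintf("  explained variance: %.4f%%\n", d$explained_variance_pct))
  cat(sprintf("  core consistency:   %.2f%%\n", d$core_consistency_pct))
  cat("  iterations:", d$n_iterations,
      if (d$converged) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$grid)) {
    pk <- component_peaks(x)
    cat("  peaks (em/ex nm):",
        paste(sprintf("%g/%g", pk$em_peak_nm, pk$ex_peak_nm),
              collapse = ", "), "\n")
  }
  invisible(x)
}

reconstruct_sse <- function(model, cube) {
  unf <- unfold_cube(cube$data)
  A <- model$scores; B <- model$em_loadings; C <- model$ex_loadings
  H <- unf$m1 %*% khatri_rao(C, B)
  sum(cube$data^2) - 2 * sum(A * H) +
    sum(crossprod(A) * (crossprod(C) * crossprod(B)))
}

#' Percentage of variance explained by a PARAFAC model
#'
#' Returns \code{100 * (1 - SSE / SS_total)} with the total sum of
#' squares taken on the raw (uncentered) cube.
#'
#' @param model a \code{parafac_model}
#' @param cube the (complete) \code{eem_cube} it was fitted to
#' @return explained variance in percent
#' @export
explained_variance <- function(model, cube) {
  stopifnot(inherits(model, "parafac_model"), inherits(cube, "eem_cube"))
  ssX <- sum(cube$data^2)
  if (ssX == 0) stop("explained variance undefined for an all-zero cube")
  100 * (1 - max(reconstruct_sse(model, cube), 0) / ssX)
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Computes the least-squares Tucker core of the cube given the model's
#' fixed factor matrices and measures its closeness to the superidentity:
#' \code{100 * (1 - sum((G - T)^2) / sum(T^2))}. Values near 100 indicate
#' the trilinear structure is appropriate; strongly lower values indicate
#' overfactoring.
#'
#' @inheritParams explained_variance
#' @return core consistency in percent (can be negative)
#' @export
corcondia <- function(model, cube) {
  stopifnot(inherits(model, "parafac_model"), inherits(cube, "eem_cube"))
  A <- model$scores; B <- model$em_loadings; C <- model$ex_loadings
  F <- model$F
  rk <- function(M) qr(M)$rank
  if (rk(A) < F || rk(B) < F || rk(C) < F)
    warning("rank-deficient factor matrix; using pseudo-inverse core solve")
  G <- ttm(ttm(ttm(cube$data, pinv(A), 1), pinv(B), 2), pinv(C), 3)
  Tsuper <- array(0, c(F, F, F))
  for (f in seq_len(F)) Tsuper[f, f, f] <- 1
  100 * (1 - sum((G - Tsuper)^2) / F)
}

#' Tucker congruence coefficient between loading vectors
#'
#' Cosine similarity between columns of two equally sized matrices,
#' returned as a cross matrix.
#'
#' @param X,Y matrices with the same number of rows
#' @return matrix of congruences, \code{ncol(X)} x \code{ncol(Y)}
#' @export
congruence <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  nx <- sqrt(colSums(X^2)); ny <- sqrt(colSums(Y^2))
  crossprod(X, Y) / outer(pmax(nx, .Machine$double.eps),
                          pmax(ny, .Machine$double.eps))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p + (p >= i)
    cbind(rep(i, nrow(q)), q)
  }))
}

#' Match components between two PARAFAC models
#'
#' Finds the one-to-one assignment of components of \code{model_b} to
#' components of \code{model_a} maximizing the summed Tucker congruence
#' of the chosen loading mode(s). The assignment is exact (all
#' permutations are scored), not greedy.
#'
#' @param model_a,model_b \code{parafac_model} objects, or any lists with
#'   \code{em_loadings}/\code{ex_loadings} matrices, with equal component
#'   counts
#' @param mode which loadings to match on: \code{"both"} (mean of the
#'   emission and excitation congruence), \code{"em"} or \code{"ex"}
#' @return list with \code{permutation} (index into \code{model_b}'s
#'   components for each component of \code{model_a}) and \code{pairs}, a
#'   data.frame of per-pair emission, excitation and combined congruences
#' @export
match_components <- function(model_a, model_b,
                             mode = c("both", "em", "ex")) {
  mode <- match.arg(mode)
  Fa <- ncol(model_a$em_loadings); Fb <- ncol(model_b$em_loadings)
  if (Fa != Fb) stop("component counts differ (", Fa, " vs ", Fb, ")")
  if (Fa > 9) stop("exact assignment supported up to 9 components")
  cong_em <- congruence(model_a$em_loadings, model_b$em_loadings)
  cong_ex <- congruence(model_a$ex_loadings, model_b$ex_loadings)
  value <- switch(mode, em = cong_em, ex = cong_ex,
                  both = (cong_em + cong_ex) / 2)
  perms <- all_permutations(Fa)
  scores <- apply(perms, 1, function(p) sum(value[cbind(seq_len(Fa), p)]))
  best <- perms[which.max(scores), ]
  idx <- cbind(seq_len(Fa), best)
  list(permutation = as.integer(best),
       pairs = data.frame(
         component_a = seq_len(Fa), component_b = as.integer(best),
         congruence_em = cong_em[idx], congruence_ex = cong_ex[idx],
         congruence = value[idx]))
}

#' Spectral peak positions of fitted components
#'
#' @param model a \code{parafac_model} carrying its grid
#' @return data.frame with per-component emission and excitation argmax
#'   wavelengths (nm)
#' @export
component_peaks <- function(model) {
  g <- model$grid
  stopifnot(!is.null(g))
  data.frame(
    component = seq_len(model$F),
    em_peak_nm = g$em_wavelengths[apply(model$em_loadings, 2, which.max)],
    ex_peak_nm = g$ex_wavelengths[apply(model$ex_loadings, 2, which.max)])
}

#' Local maxima of one loading vector
#'
#' Returns the wavelengths of strict local maxima of a loading profile,
#' used e.g. to read off both peaks of a bimodal emission band.
#'
#' @param loading numeric profile on a wavelength axis
#' @param wavelengths the axis (nm)
#' @param min_rel_height maxima below this fraction of the global maximum
#'   are ignored (suppresses noise ripples)
#' @return numeric vector of peak wavelengths, increasing
#' @export
local_maxima <- function(loading, wavelengths,
                         min_rel_height = 0.05) {
  n <- length(loading)
  stopifnot(length(wavelengths) == n, n >= 3)
  up <- c(TRUE, diff(loading) > 0)
  down <- c(diff(loading) < 0, TRUE)
  peaks <- which(up & down)
  peaks <- peaks[loading[peaks] >= min_rel_height * max(loading)]
  wavelengths[peaks]
}
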