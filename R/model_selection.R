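## Choosing the number of PARAFAC components: residual scan over a range
## of component counts plus split-half validation with congruence
## matching of the half-model loadings.

#' Fit PARAFAC models over a range of component counts
#'
#' Fits one model per component count and tabulates residual SSE,
#' explained variance and core consistency, the diagnostics inspected
#' when deciding how many trilinear components a fluorescence cube
#' supports.
#'
#' @param cube a preprocessed \code{eem_cube}
#' @param F_range integer vector of component counts (default 1:8)
#' @param n_starts,seed,tol,max_iter passed to \code{\link{fit_parafac}};
#'   per-F seeds are derived from \code{seed}
#' @param keep_models if \code{TRUE} (default) the fitted models are
#'   returned alongside the table
#' @return object of class \code{parafac_scan}: list with \code{table}
#'   (one row per F) and \code{models}
#' @export
residual_scan <- function(cube, F_range = 1:8, n_starts = 10, seed = NULL,
                          tol = 1e-8, max_iter = 2000,
                          keep_models = TRUE) {
  stopifnot(length(F_range) >= 1, all(F_range >= 1))
  F_range <- sort(unique(as.integer(F_range)))
  models <- vector("list", length(F_range))
  names(models) <- paste0("F", F_range)
  tab <- data.frame(F = F_range, sse = NA_real_,
                    explained_variance_pct = NA_real_,
                    core_consistency_pct = NA_real_,
                    converged = NA)
  for (i in seq_along(F_range)) {
    m <- fit_parafac(cube, F_range[i], n_starts = n_starts,
                     seed = if (is.null(seed)) NULL else seed + F_range[i],
                     tol = tol, max_iter = max_iter)
    tab$sse[i] <- m$diagnostics$sse
    tab$explained_variance_pct[i] <- m$diagnostics$explained_variance_pct
    tab$core_consistency_pct[i] <- m$diagnostics$core_consistency_pct
    tab$converged[i] <- m$diagnostics$converged
    models[[i]] <- m
  }
  structure(list(table = tab, models = if (keep_models) models),
            class = "parafac_scan")
}

#' @export
print.parafac_scan <- function(x, ...) {
  cat("PARAFAC residual scan:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

resolve_halves <- function(cube, split_by) {
  if (is.list(split_by)) {
    stopifnot(length(split_by) == 2)
    h1 <- split_by[[1]]; h2 <- split_by[[2]]
    idx <- sort(c(h1, h2))
    if (!identical(as.integer(idx), seq_len(nrow(cube$samples))))
      stop("explicit halves must partition the sample set")
    return(list(h1, h2))
  }
  if (!split_by %in% names(cube$samples))
    stop("no metadata field '", split_by, "' to split by")
  vals <- cube$samples[[split_by]]
  u <- unique(vals)
  if (length(u) == 2) {
    list(which(vals == u[1]), which(vals == u[2]))
  } else {
    # stratified alternation within levels of the field
    h1 <- integer(0)
    for (lev in u) {
      w <- which(vals == lev)
      h1 <- c(h1, w[seq_along(w) %% 2 == 1])
    }
    list(sort(h1), setdiff(seq_along(vals), h1))
  }
}

#' Split-half validation of PARAFAC component counts
#'
#' Splits the cube into two halves, fits independent models on each half
#' for every candidate component count, matches the half-model loadings
#' by Tucker congruence, and flags a component count as validated when
#' every matched pair agrees (congruence at or above \code{threshold}) in
#' both the emission and the excitation mode. A stable chemical model
#' should reproduce its loadings from either half of the samples.
#'
#' @param cube a preprocessed \code{eem_cube}
#' @param split_by metadata column name used to form the halves (e.g.
#'   \code{"cell_line"}), or a list of two integer index vectors
#' @param F_range candidate component counts
#' @param threshold minimum matched congruence for a pass (default 0.95)
#' @param n_starts,seed,tol,max_iter fit options, as in
#'   \code{\link{fit_parafac}}
#' @return object of class \code{split_half_result}: list with
#'   \code{table} (per F: minimum and mean matched congruence per mode
#'   and the pass flag), \code{pairs} (per-F matched-pair details),
#'   \code{halves} and \code{threshold}
#' @export
split_half <- function(cube, split_by = "cell_line", F_range = 1:8,
                       threshold = 0.95, n_starts = 10, seed = NULL,
                       tol = 1e-8, max_iter = 2000) {
  halves <- resolve_halves(cube, split_by)
  if (any(lengths(halves) == 0)) stop("each half must be nonempty")
  cube1 <- subset_cube(cube, halves[[1]])
  cube2 <- subset_cube(cube, halves[[2]])
  F_range <- sort(unique(as.integer(F_range)))
  bad <- F_range[F_range > min(lengths(halves))]
  if (length(bad))
    stop("half size ", min(lengths(halves)),
         " is smaller than requested component count(s) ",
         paste(bad, collapse = ", "))
  tab <- data.frame(F = F_range,
                    min_congruence_em = NA_real_,
                    min_congruence_ex = NA_real_,
                    mean_congruence = NA_real_,
                    pass = NA)
  pairs <- vector("list", length(F_range))
  names(pairs) <- paste0("F", F_range)
  for (i in seq_along(F_range)) {
    Fi <- F_range[i]
    s1 <- if (is.null(seed)) NULL else seed + 1000L + Fi
    s2 <- if (is.null(seed)) NULL else seed + 2000L + Fi
    m1 <- fit_parafac(cube1, Fi, n_starts = n_starts, seed = s1,
                      tol = tol, max_iter = max_iter)
    m2 <- fit_parafac(cube2, Fi, n_starts = n_starts, seed = s2,
                      tol = tol, max_iter = max_iter)
    mm <- match_components(m1, m2, mode = "both")
    tab$min_congruence_em[i] <- min(mm$pairs$congruence_em)
    tab$min_congruence_ex[i] <- min(mm$pairs$congruence_ex)
    tab$mean_congruence[i] <- mean(mm$pairs$congruence)
    tab$pass[i] <- tab$min_congruence_em[i] >= threshold &&
      tab$min_congruence_ex[i] >= threshold
    pairs[[i]] <- mm$pairs
  }
  structure(list(table = tab, pairs = pairs, halves = halves,
                 threshold = threshold),
            class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat("Split-half validation (threshold", x$threshold, "):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Select the number of PARAFAC components
#'
#' Combines a residual scan and a split-half result over the same range
#' of component counts: the chosen count is the largest F that (a)
#' passes split-half validation and (b) still improves the explained
#' variance over F - 1 by more than \code{gain_tol} percentage points.
#' Components beyond the true chemical rank mostly fit noise, adding
#' negligible explained variance and failing to reproduce across halves.
#'
#' @param scan a \code{parafac_scan}
#' @param splithalf a \code{split_half_result} on the same F range
#' @param gain_tol minimum marginal explained-variance gain (percentage
#'   points) for a component count to stay a candidate (default 0.02)
#' @return object of class \code{component_selection}: list with
#'   \code{F} (the chosen count) and \code{rationale}, a per-F table of
#'   gains, split-half verdicts and candidacy
#' @export
select_n_components <- function(scan, splithalf, gain_tol = 0.02) {
  stopifnot(inherits(scan, "parafac_scan"),
            inherits(splithalf, "split_half_result"))
  if (!identical(scan$table$F, splithalf$table$F))
    stop("scan and split-half cover different F ranges")
  ev <- scan$table$explained_variance_pct
  gain <- c(ev[1], diff(ev))  # gain over the empty (zero-component) model
  rationale <- data.frame(
    F = scan$table$F,
    explained_variance_pct = ev,
    gain_pct_points = gain,
    splithalf_pass = splithalf$table$pass,
    candidate = splithalf$table$pass & gain > gain_tol)
  if (!any(rationale$candidate))
    stop("no component count passes both criteria; diagnostics:\n",
         paste(utils::capture.output(print(rationale)), collapse = "\n"))
  chosen <- max(rationale$F[rationale$candidate])
  flagged <- chosen == max(rationale$F) &&
    all(rationale$candidate)
  structure(list(F = as.integer(chosen), rationale = rationale,
                 at_range_edge = flagged, gain_tol = gain_tol),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat("Selected", x$F, "components\n")
  if (x$at_range_edge)
    cat("  note: every scanned count was a candidate;",
        "the range may be too narrow\n")
  print(x$rationale, row.names = FALSE)
  invisible(x)
}
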