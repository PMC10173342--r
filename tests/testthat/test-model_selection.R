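test_that("residual scan reports one model per requested component count", {
  sim <- small_study_cube(n_replicates = 2, seed = 3)
  scan <- suppressWarnings(
    residual_scan(sim$cube, 1:4, n_starts = 2, seed = 1))
  expect_identical(scan$table$F, 1:4)
  expect_length(scan$models, 4)
  expect_true(all(diff(scan$table$sse) <= 1e-6 * scan$table$sse[1]))
  expect_true(all(diff(scan$table$explained_variance_pct) >= -1e-8))
})

test_that("exact low-rank cubes saturate the scan at the true rank", {
  fac <- rand_cp_factors(10, 8, 6, 2, 71)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  scan <- suppressWarnings(
    residual_scan(cube, 1:3, n_starts = 3, seed = 2))
  expect_lt(scan$table$explained_variance_pct[1], 100 - 1e-6)
  expect_gte(scan$table$explained_variance_pct[2], 100 - 1e-6)
  expect_gte(scan$table$explained_variance_pct[3], 100 - 1e-6)
})

test_that("identical halves pass split-half at every component count", {
  fac <- rand_cp_factors(6, 8, 7, 2, 81)
  dup <- cp_cube(rbind(fac$A, fac$A), fac$B, fac$C)
  sh <- split_half(dup, split_by = list(1:6, 7:12), F_range = 1:2,
                   n_starts = 2, seed = 4)
  expect_true(all(sh$table$pass))
  expect_true(all(sh$table$min_congruence_em >= 0.9999))
  expect_true(all(sh$table$min_congruence_ex >= 0.9999))
})

test_that("split-half input validation", {
  fac <- rand_cp_factors(8, 6, 5, 1, 91)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  expect_error(split_half(cube, split_by = list(1:4, 4:8)),
               "partition")
  expect_error(split_half(cube, split_by = "no_such_field"),
               "metadata")
  expect_error(split_half(cube, split_by = list(1:4, 5:8), F_range = 1:6),
               "smaller than")
})

test_that("rank-1 cube: split-half near-perfect and selection returns 1", {
  fac <- rand_cp_factors(12, 7, 6, 1, 101)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  scan <- suppressWarnings(
    residual_scan(cube, 1:2, n_starts = 2, seed = 5))
  sh <- suppressWarnings(
    split_half(cube, split_by = list(1:6, 7:12), F_range = 1:2,
               n_starts = 2, seed = 5))
  expect_true(sh$table$pass[1])
  expect_gte(sh$table$min_congruence_em[1], 0.999999)
  sel <- select_n_components(scan, sh)
  expect_identical(sel$F, 1L)
})

test_that("selection picks the largest validated, still-informative count", {
  mk_scan <- function(ev) {
    structure(list(table = data.frame(
      F = seq_along(ev), sse = 100 - ev, explained_variance_pct = ev,
      core_consistency_pct = 100, converged = TRUE), models = NULL),
      class = "parafac_scan")
  }
  mk_sh <- function(pass) {
    structure(list(table = data.frame(
      F = seq_along(pass), min_congruence_em = ifelse(pass, 0.99, 0.5),
      min_congruence_ex = ifelse(pass, 0.99, 0.5),
      mean_congruence = 0.9, pass = pass), pairs = NULL,
      halves = NULL, threshold = 0.95),
      class = "split_half_result")
  }
  # marginal gain beyond F = 3 below tolerance; split-half passes to 4
  sel <- select_n_components(mk_scan(c(70, 90, 99, 99.005)),
                             mk_sh(c(TRUE, TRUE, TRUE, TRUE)))
  expect_identical(sel$F, 3L)
  expect_false(sel$at_range_edge)
  # split-half caps the choice even with large gains
  sel2 <- select_n_components(mk_scan(c(70, 90, 99, 99.9)),
                              mk_sh(c(TRUE, TRUE, FALSE, FALSE)))
  expect_identical(sel2$F, 2L)
  # pathological: everything passes with large gains -> top of range,
  # flagged
  sel3 <- select_n_components(mk_scan(c(70, 90, 95, 99)),
                              mk_sh(rep(TRUE, 4)))
  expect_identical(sel3$F, 4L)
  expect_true(sel3$at_range_edge)
  # nothing passes -> error with diagnostics
  expect_error(select_n_components(mk_scan(c(70, 70.001)),
                                   mk_sh(c(FALSE, FALSE))),
               "no component count")
  # mismatched ranges refused
  expect_error(select_n_components(mk_scan(c(70, 90)), mk_sh(c(TRUE))),
               "different F ranges")
})

test_that("true component count is recovered on small study cubes", {
  # scaled-down parameter-recovery check: 5-component truth, fewer
  # replicates than the full design
  sim <- small_study_cube(n_replicates = 3, seed = 17)
  scan <- suppressWarnings(
    residual_scan(sim$cube, 3:6, n_starts = 3, seed = 17))
  sh <- suppressWarnings(
    split_half(sim$cube, split_by = "cell_line", F_range = 3:6,
               n_starts = 3, seed = 17))
  sel <- select_n_components(scan, sh)
  expect_identical(sel$F, 5L)
})

test_that("sample order inside halves does not change the choice", {
  fac <- rand_cp_factors(12, 7, 6, 2, 111)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  sh1 <- split_half(cube, split_by = list(1:6, 7:12), F_range = 1:2,
                    n_starts = 2, seed = 6)
  set.seed(7)
  perm <- c(sample(1:6), sample(7:12))
  cube_p <- subset_cube(cube, perm)
  sh2 <- split_half(cube_p, split_by = list(1:6, 7:12), F_range = 1:2,
                    n_starts = 2, seed = 6)
  scan <- suppressWarnings(
    residual_scan(cube, 1:2, n_starts = 2, seed = 6))
  scan_p <- suppressWarnings(
    residual_scan(cube_p, 1:2, n_starts = 2, seed = 6))
  expect_identical(select_n_components(scan, sh1)$F,
                   select_n_components(scan_p, sh2)$F)
})
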