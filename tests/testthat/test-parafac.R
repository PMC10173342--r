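test_that("exact trilinear tensors are recovered at the true rank", {
  # rank-2 and rank-3 cases, uniqueness up to permutation/scale
  for (case in list(list(F = 2, seed = 11), list(F = 3, seed = 12))) {
    fac <- rand_cp_factors(9, 8, 6, case$F, case$seed)
    cube <- cp_cube(fac$A, fac$B, fac$C)
    m <- fit_parafac(cube, case$F, n_starts = 4, seed = 1)
    expect_gte(m$diagnostics$explained_variance_pct, 99.9999)
    expect_congruent(m, list(em_loadings = fac$B, ex_loadings = fac$C),
                     0.999)
  }
})

test_that("rank-1 tensors give essentially exact loadings", {
  fac <- rand_cp_factors(6, 7, 5, 1, seed = 21)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  m <- fit_parafac(cube, 1, n_starts = 2, seed = 1)
  expect_gte(congruence(m$em_loadings, fac$B)[1, 1], 0.999999)
  expect_gte(congruence(m$ex_loadings, fac$C)[1, 1], 0.999999)
})

test_that("ALS residual trace is monotone non-increasing", {
  for (seed in 1:3) {
    fac <- rand_cp_factors(8, 7, 6, 3, seed)
    cube <- cp_cube(fac$A, fac$B, fac$C)
    set.seed(seed + 100)
    cube$data <- cube$data + array(rnorm(length(cube$data), 0, 0.05),
                                   dim(cube$data))
    cube$data <- pmax(cube$data, 0)
    m <- fit_parafac(cube, 3, n_starts = 3, seed = seed)
    expect_true(all(diff(m$diagnostics$sse_trace) <= 1e-8))
  }
})

test_that("factors are non-negative and in canonical form", {
  sim <- small_study_cube(n_replicates = 2, seed = 9)
  m <- fit_parafac(sim$cube, 3, n_starts = 2, seed = 2)
  expect_gte(min(m$scores), 0)
  expect_gte(min(m$em_loadings), 0)
  expect_gte(min(m$ex_loadings), 0)
  expect_equal(colSums(m$em_loadings^2), rep(1, 3), tolerance = 1e-10)
  expect_equal(colSums(m$ex_loadings^2), rep(1, 3), tolerance = 1e-10)
  expect_true(all(diff(colSums(m$scores^2)) <= 1e-8))  # energy-ordered
})

test_that("fit is deterministic given cube, F, seed and n_starts", {
  fac <- rand_cp_factors(8, 7, 6, 2, 31)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  set.seed(77)
  cube$data <- cube$data + array(rnorm(length(cube$data), 0, 0.02),
                                 dim(cube$data))
  cube$data <- pmax(cube$data, 0)
  m1 <- fit_parafac(cube, 2, n_starts = 5, seed = 4)
  m2 <- fit_parafac(cube, 2, n_starts = 5, seed = 4)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$em_loadings, m2$em_loadings)
  expect_identical(m1$ex_loadings, m2$ex_loadings)
})

test_that("fit rejects incomplete or non-finite cubes", {
  sim <- generate_cube(list(design = generate_design(1)), seed = 2)
  expect_error(fit_parafac(sim$cube, 2), "preprocess")
  cube <- suppressWarnings(preprocess_cube(sim$cube))
  cube$data[1] <- Inf
  expect_error(fit_parafac(cube, 2), "non-finite")
})

test_that("explained variance follows its defining ratio", {
  # cube with SS_total = 100 and a model leaving SSE = 1 -> 99.0%
  J <- 5; K <- 4
  data <- array(0, c(3, J, K)); data[1, 1, 1] <- 10
  cube <- eemviva:::new_eem_cube(toy_grid(J, K), data, toy_meta(3),
                                 preprocessed = TRUE)
  model <- structure(
    list(F = 1L, scores = matrix(c(9, 0, 0), 3, 1),
         em_loadings = matrix(c(1, rep(0, J - 1)), J, 1),
         ex_loadings = matrix(c(1, rep(0, K - 1)), K, 1),
         grid = cube$grid),
    class = "parafac_model")
  expect_equal(explained_variance(model, cube), 99.0)

  # all-zero model on a nonzero cube -> 0; exact model -> 100
  zero_model <- model
  zero_model$scores[] <- 0
  expect_equal(explained_variance(zero_model, cube), 0)
  exact <- model
  exact$scores[1, 1] <- 10
  expect_equal(explained_variance(exact, cube), 100)

  cube$data[] <- 0
  expect_error(explained_variance(model, cube), "all-zero")
})

test_that("CORCONDIA is 100 for exact trilinear data and LS rank-1 fits", {
  fac <- rand_cp_factors(7, 6, 5, 2, 41)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  m2 <- fit_parafac(cube, 2, n_starts = 3, seed = 1)
  expect_equal(corcondia(m2, cube), 100, tolerance = 1e-6)

  # any globally LS-fitted one-component model has scalar core exactly 1
  noisy <- cube
  set.seed(42)
  noisy$data <- pmax(noisy$data +
                       array(rnorm(length(noisy$data), 0, 0.05),
                             dim(noisy$data)), 0)
  m1 <- fit_parafac(noisy, 1, n_starts = 2, seed = 1)
  expect_equal(corcondia(m1, noisy), 100, tolerance = 1e-6)
})

test_that("CORCONDIA matches a brute-force normal-equations core solve", {
  # overfactored fit of an exact rank-1 tensor
  fac <- rand_cp_factors(6, 5, 4, 1, 51)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  m <- suppressWarnings(fit_parafac(cube, 2, n_starts = 3, seed = 3,
                                    max_iter = 500))
  cc <- suppressWarnings(corcondia(m, cube))
  # independent oracle: solve vec(X) = (C (x) B (x) A) vec(G) by least
  # squares with an explicit Kronecker design
  G <- core_oracle(m, cube)
  Tsup <- array(0, c(2, 2, 2)); Tsup[1, 1, 1] <- Tsup[2, 2, 2] <- 1
  cc_oracle <- 100 * (1 - sum((G - Tsup)^2) / 2)
  expect_equal(cc, cc_oracle, tolerance = 1e-8)
})

test_that("component matching finds exact assignments", {
  sim <- small_study_cube(n_replicates = 2, seed = 13)
  m <- fit_parafac(sim$cube, 3, n_starts = 2, seed = 5)

  self <- match_components(m, m)
  expect_identical(self$permutation, 1:3)
  expect_equal(self$pairs$congruence, rep(1, 3), tolerance = 1e-12)

  swapped <- m
  perm <- c(3, 1, 2)
  swapped$scores <- m$scores[, perm]
  swapped$em_loadings <- m$em_loadings[, perm]
  swapped$ex_loadings <- m$ex_loadings[, perm]
  mm <- match_components(m, swapped)
  expect_identical(mm$permutation, order(perm))
  expect_equal(mm$pairs$congruence, rep(1, 3), tolerance = 1e-12)

  expect_error(match_components(m, list(em_loadings = m$em_loadings[, 1:2],
                                        ex_loadings = m$ex_loadings[, 1:2])),
               "component counts differ")
})

test_that("independent refits of an exact tensor agree after matching", {
  fac <- rand_cp_factors(9, 8, 7, 3, 61)
  cube <- cp_cube(fac$A, fac$B, fac$C)
  ma <- fit_parafac(cube, 3, n_starts = 3, seed = 101)
  mb <- fit_parafac(cube, 3, n_starts = 3, seed = 202)
  expect_congruent(ma, mb, 0.999)
})

test_that("local_maxima reads off bimodal peaks", {
  g <- build_acquisition_grid()
  protos <- default_prototypes(g)
  pk <- local_maxima(protos[[4]]$em_profile, g$em_wavelengths)
  expect_identical(pk, c(520L, 590L))
})
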