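test_that("default prototypes sit at the nominal spectral maxima", {
  g <- build_acquisition_grid()
  pr <- default_prototypes(g)
  expect_length(pr, 5)
  em <- g$em_wavelengths; ex <- g$ex_wavelengths
  expect_identical(em[which.max(pr[[1]]$em_profile)], 330L)
  expect_identical(ex[which.max(pr[[1]]$ex_profile)], 290L)
  expect_identical(ex[which.max(pr[[2]]$ex_profile)], 280L)
  expect_lt(em[which.max(pr[[2]]$em_profile)], 325L)
  expect_identical(em[which.max(pr[[3]]$em_profile)], 380L)
  expect_identical(ex[which.max(pr[[3]]$ex_profile)], 300L)
  expect_identical(local_maxima(pr[[4]]$em_profile, em), c(520L, 590L))
  expect_identical(local_maxima(pr[[4]]$ex_profile, ex), c(390L, 440L))
  expect_identical(em[which.max(pr[[5]]$em_profile)], 450L)
  expect_identical(ex[which.max(pr[[5]]$ex_profile)], 360L)
  for (p in pr) {
    expect_true(all(p$em_profile >= 0) && all(p$ex_profile >= 0))
    expect_equal(sum(p$em_profile^2), 1, tolerance = 1e-12)
    expect_equal(sum(p$ex_profile^2), 1, tolerance = 1e-12)
  }
})

test_that("prototype constructor enforces the Stokes shift", {
  g <- build_acquisition_grid()
  expect_error(
    fluorophore_prototype("bad", band(400), band(350), g),
    "Stokes")
  expect_warning(
    fluorophore_prototype("edge", band(280), band(700), g),
    "outside")
})

test_that("the default design is 2 lines x 6 doses x 12 replicates", {
  d <- generate_design()
  expect_identical(nrow(d), 144L)
  for (cl in c("A375", "HaCaT")) {
    doses <- unique(d$dose_uM[d$cell_line == cl])
    expect_length(doses, 6)
    expect_true(0 %in% doses)
  }
  expect_identical(sum(d$cell_line == "A375" & d$dose_uM == 250), 12L)
  expect_false(anyDuplicated(d[c("cell_line", "dose_uM", "replicate")]) > 0)
})

test_that("viability map returns the reference values and rejects unknowns", {
  expect_equal(viability_map("A375", 0), 100)
  expect_equal(viability_map("A375", 500), 10)
  expect_equal(viability_map("HaCaT", 250), 50)
  expect_equal(viability_map(c("A375", "HaCaT"), c(5, 5)), c(90, 90))
  expect_error(viability_map("A375", 77), "unknown")
})

test_that("score trajectories are monotone in viability and reproducible", {
  d <- generate_design()
  v <- viability_map(d$cell_line, d$dose_uM)
  s0 <- generate_scores(d, v, noise_cv = 0)
  expect_equal(cor(s0[, 1], v, method = "spearman"), 1)
  expect_equal(cor(s0[, 2], v, method = "spearman"), -1)
  expect_true(all(s0 >= 0))

  s1 <- generate_scores(d, v, seed = 5)
  s2 <- generate_scores(d, v, seed = 5)
  expect_identical(s1, s2)

  bad <- default_trend_params()
  bad$slope[1] <- -bad$slope[1]
  expect_error(generate_scores(d, v, trend_params = bad), "slope")
  expect_silent(generate_scores(d, v, trend_params = bad,
                                allow_any_slopes = TRUE, seed = 1))

  # per-group mean ordering tracks viability at default noise; dose
  # groups sharing the same viability (e.g. the two saturating doses)
  # are pooled before checking the ordering
  sgn <- sign(default_trend_params()$slope)
  for (seed in 1:3) {
    s <- generate_scores(d, v, seed = seed)
    for (cl in c("A375", "HaCaT")) {
      idx <- d$cell_line == cl
      for (f in 1:5) {
        gm <- tapply(s[idx, f], v[idx], mean)  # grouped by viability
        gv <- as.numeric(names(gm))
        expect_true(all(diff(sgn[f] * gm[order(gv)]) > 0),
                    label = paste(cl, "component", f, "seed", seed))
      }
    }
  }
})

test_that("generated cubes are masked trilinear signal plus noise", {
  sim0 <- generate_cube(list(design = generate_design(1),
                             noise_rms_frac = 0), seed = 6)
  g <- sim0$cube$grid
  tr <- sim0$truth
  kr <- sapply(1:5, function(f)
    kronecker(tr$ex_loadings[, f], tr$em_loadings[, f]))
  X_true <- array(tcrossprod(tr$scores, kr), dim(sim0$cube$data))
  meas <- rep(g$measured_mask, each = dim(sim0$cube)[1])
  expect_equal(sim0$cube$data[meas], X_true[meas], tolerance = 1e-12)
  expect_true(all(is.na(sim0$cube$data[!meas])))

  sim <- generate_cube(seed = 7)
  expect_identical(dim(sim$cube), c(144L, 71L, 26L))

  simA <- generate_cube(seed = 8)
  simB <- generate_cube(seed = 9)
  expect_identical(simA$truth$em_loadings, simB$truth$em_loadings)
  expect_identical(simA$truth$ex_loadings, simB$truth$ex_loadings)
  expect_false(identical(simA$cube$data, simB$cube$data))
  # same seed -> identical cube
  expect_identical(generate_cube(seed = 8)$cube$data, simA$cube$data)
})

test_that("MTT reference groups are self-normalized to the control", {
  d <- generate_design()
  m0 <- mtt_reference(d, cv = 0, seed = 1)
  expect_equal(
    m0$summary$mean,
    viability_map(m0$summary$cell_line, m0$summary$dose_uM),
    tolerance = 1e-12)
  expect_equal(m0$summary$sd, rep(0, 12), tolerance = 1e-12)

  m <- mtt_reference(d, seed = 2)
  expect_true(all(m$summary$n == 5))
  expect_identical(nrow(m$replicates), 60L)
  for (cl in c("A375", "HaCaT")) {
    ctrl <- m$replicates$cell_line == cl & m$replicates$dose_uM == 0
    expect_equal(mean(m$replicates$viability_pct[ctrl]), 100,
                 tolerance = 1e-12)
  }
})
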