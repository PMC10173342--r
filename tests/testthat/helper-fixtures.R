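# Fixture builders shared across the suite. All synthetic tensors are
# generated in code under fixed seeds; nothing is read from disk.

# fully measured grid with J emission / K excitation points
toy_grid <- function(J, K) {
  build_acquisition_grid(
    ex_start = 250, ex_end = 250 + 10 * (K - 1), ex_step = 10,
    em_max = 300 + 5 * (J - 1), em_step = 5,
    gap = 20, em_floor = 300, floor_threshold = 1e6)
}

toy_meta <- function(I) {
  data.frame(sample_id = sprintf("s%02d", seq_len(I)),
             cell_line = rep(c("A375", "HaCaT"), length.out = I),
             dose_uM = rep(c(0, 5, 50), length.out = I),
             replicate = seq_len(I))
}

# cube from explicit CP factors (exact trilinear, fully measured)
cp_cube <- function(A, B, C) {
  I <- nrow(A); J <- nrow(B); K <- nrow(C)
  kr <- sapply(seq_len(ncol(A)), function(f) kronecker(C[, f], B[, f]))
  data <- array(tcrossprod(A, kr), c(I, J, K))
  eemviva:::new_eem_cube(toy_grid(J, K), data, toy_meta(I),
                         preprocessed = TRUE)
}

# random non-negative CP factors, bounded away from degeneracy
rand_cp_factors <- function(I, J, K, F, seed) {
  set.seed(seed)
  list(A = matrix(runif(I * F, 0.2, 2), I, F),
       B = matrix(runif(J * F, 0.1, 1), J, F),
       C = matrix(runif(K * F, 0.1, 1), K, F))
}

# small default-structure study cube (full 71 x 26 grid, fewer
# replicates than the default design to keep fits quick)
small_study_cube <- function(n_replicates = 3, seed = 1, ...) {
  sim <- generate_cube(
    utils::modifyList(list(design = generate_design(n_replicates)),
                      list(...)),
    seed = seed)
  list(cube = suppressWarnings(preprocess_cube(sim$cube)),
       truth = sim$truth)
}

expect_congruent <- function(model, truth, min_cong, mode = "both") {
  mm <- match_components(model, truth, mode = mode)
  expect_true(all(mm$pairs$congruence_em >= min_cong) &&
                all(mm$pairs$congruence_ex >= min_cong),
              label = paste("matched congruences",
                            paste(round(mm$pairs$congruence, 6),
                                  collapse = ", ")))
  invisible(mm)
}
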