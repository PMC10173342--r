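## Synthetic EEM study generator: five Gaussian-band fluorophore
## prototypes at literature peak positions, a two-cell-line dose design,
## viability-linked score trajectories, trilinear cubes with acquisition
## masking, and a simulated MTT reference.

#' Construct a fluorophore prototype
#'
#' A prototype is a pair of spectral profiles, each a positive sum of
#' (possibly asymmetric) Gaussian bands evaluated on the grid axes and
#' normalized to unit Euclidean norm. Each band has independent widths
#' below and above its center, so profiles can carry the asymmetry of
#' real fluorescence spectra: emission bands rise steeply on the blue
#' side of the maximum and tail off to the red, excitation (absorption)
#' bands mirror this with a steep red edge. The band mode sits exactly
#' at \code{center}, whatever the asymmetry. Emission band centers must
#' lie above excitation band centers (Stokes shift).
#'
#' @param name label
#' @param ex_bands,em_bands data.frames with columns \code{center},
#'   \code{width_lo}, \code{width_hi}, \code{weight} (nm, nm, nm, > 0);
#'   see \code{\link{band}}
#' @param grid an \code{eem_grid} the profiles are evaluated on
#' @return object of class \code{fluorophore_prototype} with unit-norm
#'   \code{em_profile} and \code{ex_profile} vectors
#' @export
fluorophore_prototype <- function(name, ex_bands, em_bands, grid) {
  ex_bands <- as.data.frame(ex_bands); em_bands <- as.data.frame(em_bands)
  stopifnot(nrow(ex_bands) >= 1, nrow(em_bands) >= 1,
            all(ex_bands$weight > 0), all(em_bands$weight > 0),
            all(ex_bands$width_lo > 0), all(em_bands$width_lo > 0),
            all(ex_bands$width_hi > 0), all(em_bands$width_hi > 0))
  if (min(em_bands$center) <= max(ex_bands$center))
    stop("emission band centers must exceed excitation band centers ",
         "(Stokes shift) for '", name, "'")
  eval_bands <- function(bands, axis, axis_name) {
    out_of_axis <- bands$center < min(axis) | bands$center > max(axis)
    if (any(out_of_axis))
      warning("band center(s) ",
              paste(bands$center[out_of_axis], collapse = ", "),
              " nm of '", name, "' lie outside the ", axis_name, " axis")
    p <- rep(0, length(axis))
    for (b in seq_len(nrow(bands))) {
      w <- ifelse(axis < bands$center[b], bands$width_lo[b],
                  bands$width_hi[b])
      p <- p + bands$weight[b] *
        exp(-(axis - bands$center[b])^2 / (2 * w^2))
    }
    p / sqrt(sum(p^2))
  }
  structure(
    list(name = name, ex_bands = ex_bands, em_bands = em_bands,
         em_profile = eval_bands(em_bands, grid$em_wavelengths,
                                 "emission"),
         ex_profile = eval_bands(ex_bands, grid$ex_wavelengths,
                                 "excitation")),
    class = "fluorophore_prototype")
}

#' Spectral band specification
#'
#' @param center band mode (nm)
#' @param width one width (symmetric band) or \code{c(lo, hi)}: Gaussian
#'   sigma below/above the center (nm)
#' @param weight band weight (> 0)
#' @return one-row data.frame usable in
#'   \code{\link{fluorophore_prototype}}
#' @export
band <- function(center, width = 20, weight = 1) {
  width <- rep(width, length.out = 2)
  data.frame(center = center, width_lo = width[1], width_hi = width[2],
             weight = weight)
}

#' Default five-fluorophore prototype set
#'
#' Five cell-culture fluorophore prototypes at the spectral maxima
#' typical of intrinsic cellular fluorescence: a tryptophan-like protein
#' component (ex 290 / em 330 nm), a tyrosine-like component (ex 280 nm,
#' emission maximum below 325 nm), a pyridoxine-like component (ex 300 /
#' em 380 nm), a flavin-like component with bimodal excitation (390 and
#' 440 nm) and bimodal emission (520 and 590 nm), and an NADH-like
#' component (ex 360 / em 450 nm). Emission bands are asymmetric with a
#' steep blue edge and a long red tail, excitation bands the mirror
#' image (steep red edge), so essentially no trilinear signal falls at
#' or below the Rayleigh line -- real fluorophores emit no anti-Stokes
#' intensity, which is also what makes zero-insertion below the scatter
#' line a consistent preprocessing convention.
#'
#' @param grid an \code{eem_grid} (default: the standard acquisition
#'   grid)
#' @param em_widths \code{c(blue, red)} Gaussian sigmas (nm) of every
#'   emission band
#' @param ex_widths \code{c(blue, red)} sigmas (nm) of every excitation
#'   band
#' @return list of five \code{fluorophore_prototype} objects
#' @export
default_prototypes <- function(grid = build_acquisition_grid(),
                               em_widths = c(10, 28),
                               ex_widths = c(28, 10)) {
  list(
    fluorophore_prototype(
      "tryptophan-like", band(290, ex_widths), band(330, em_widths),
      grid),
    fluorophore_prototype(
      "tyrosine-like", band(280, ex_widths), band(315, em_widths),
      grid),
    fluorophore_prototype(
      "pyridoxine-like", band(300, ex_widths), band(380, em_widths),
      grid),
    fluorophore_prototype(
      "flavin-like",
      rbind(band(390, ex_widths, 1), band(440, ex_widths, 0.8)),
      rbind(band(520, em_widths, 1), band(590, em_widths, 0.7)), grid),
    fluorophore_prototype(
      "NADH-like", band(360, ex_widths), band(450, em_widths), grid))
}

#' Default two-cell-line dose design
#'
#' 2 cell lines x 6 dose groups x \code{n_replicates} replicates. Doses
#' (uM, 0 = untreated control): A375 0, 5, 50, 250, 500, 1000; HaCaT 0,
#' 5, 25, 100, 250, 500.
#'
#' @param n_replicates replicates per (cell line, dose) group
#'   (default 12)
#' @return data.frame with columns \code{sample_id}, \code{cell_line},
#'   \code{dose_uM}, \code{replicate}
#' @export
generate_design <- function(n_replicates = 12) {
  doses <- list(A375 = c(0, 5, 50, 250, 500, 1000),
                HaCaT = c(0, 5, 25, 100, 250, 500))
  rows <- do.call(rbind, lapply(names(doses), function(cl)
    expand.grid(cell_line = cl, dose_uM = doses[[cl]],
                replicate = seq_len(n_replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  rows <- rows[order(rows$cell_line, rows$dose_uM, rows$replicate), ]
  rownames(rows) <- NULL
  data.frame(
    sample_id = sprintf("%s_d%04d_r%02d", rows$cell_line,
                        as.integer(rows$dose_uM), rows$replicate),
    rows, stringsAsFactors = FALSE)
}

default_viability_table <- function() {
  data.frame(
    cell_line = rep(c("A375", "HaCaT"), each = 6),
    dose_uM = c(0, 5, 50, 250, 500, 1000,
                0, 5, 25, 100, 250, 500),
    viability_pct = c(100, 90, 80, 60, 10, 10,
                      100, 90, 70, 65, 50, 10))
}

#' Reference viability for a (cell line, dose) pair
#'
#' Dose-to-viability map (\% of control) used as the generator's ground
#' truth: approximate MTT outcomes for oxaliplatin-treated A375 and
#' HaCaT cultures over their respective dose ranges.
#'
#' @param cell_line,dose vectors (recycled) identifying the groups
#' @param table optional replacement lookup table with columns
#'   \code{cell_line}, \code{dose_uM}, \code{viability_pct}
#' @return numeric vector of viabilities (\%)
#' @export
viability_map <- function(cell_line, dose,
                          table = default_viability_table()) {
  key <- paste(cell_line, dose)
  tab_key <- paste(table$cell_line, table$dose_uM)
  idx <- match(key, tab_key)
  if (anyNA(idx))
    stop("unknown (cell_line, dose) pair(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  table$viability_pct[idx]
}

default_trend_params <- function() {
  data.frame(
    component = 1:5,
    baseline = c(20, 110, 80, 10, 15),
    slope = c(0.8, -0.8, -0.5, 0.4, 0.6))
}

#' Generate ground-truth component scores for a design
#'
#' Scores are linear in viability plus Gaussian replicate noise:
#' \code{score = baseline + slope * viability + noise}, truncated at
#' zero. Default slopes are positive for components 1, 4 and 5 (their
#' fluorophores deplete together with viable cells) and negative for
#' components 2 and 3 (their signals rise as viability falls); supplying
#' slopes that violate these directions is refused unless
#' \code{allow_any_slopes = TRUE}.
#'
#' @param design a design data.frame from \code{\link{generate_design}}
#' @param viability per-sample viability (\%); default from
#'   \code{\link{viability_map}}
#' @param trend_params data.frame with columns \code{component},
#'   \code{baseline}, \code{slope}
#' @param noise_cv coefficient of variation of the replicate noise
#'   relative to each noise-free score (default 0.03)
#' @param drift_per_replicate optional relative drift per replicate
#'   index (default 0 = off), emulating a slow instrumental trend
#' @param inner_filter if \code{TRUE}, attenuates component 3 by 20\% in
#'   groups with viability below 20\% (inner-filter-like saturation);
#'   default off
#' @param allow_any_slopes disable the slope-direction check
#' @param seed integer seed
#' @return I x F matrix of non-negative true scores
#' @export
generate_scores <- function(design,
                            viability = viability_map(design$cell_line,
                                                      design$dose_uM),
                            trend_params = default_trend_params(),
                            noise_cv = 0.03,
                            drift_per_replicate = 0,
                            inner_filter = FALSE,
                            allow_any_slopes = FALSE,
                            seed = NULL) {
  stopifnot(nrow(design) == length(viability))
  tp <- trend_params[order(trend_params$component), ]
  Fn <- nrow(tp)
  if (!allow_any_slopes && Fn == 5) {
    expected <- c(1, -1, -1, 1, 1)
    if (any(sign(tp$slope) != expected))
      stop("slope directions must be + - - + + for components 1..5 ",
           "(set allow_any_slopes = TRUE to override)")
  }
  mu <- outer(rep(1, nrow(design)), tp$baseline) +
    outer(viability, tp$slope)
  mu <- mu * (1 + drift_per_replicate * (design$replicate - 1))
  if (inner_filter && Fn >= 3)
    mu[viability < 20, 3] <- mu[viability < 20, 3] * 0.8
  noise <- with_seed(seed,
    matrix(stats::rnorm(length(mu), 0, 1), nrow(mu)) * abs(mu) * noise_cv)
  pmax(mu + noise, 0)
}

#' Generate a masked synthetic EEM cube with its ground truth
#'
#' Builds the trilinear cube \code{sum_f score_f x em_profile_f x
#' ex_profile_f} from the prototype set and viability-linked scores,
#' adds independent Gaussian measurement noise with RMS equal to
#' \code{noise_rms_frac} times the signal RMS over the measured region,
#' then deletes the cells outside the acquisition mask (to be restored
#' by \code{\link{preprocess_cube}}).
#'
#' @param config optional list overriding any of: \code{grid},
#'   \code{prototypes}, \code{design}, \code{viability_table},
#'   \code{trend_params}, \code{noise_rms_frac} (default 0.001),
#'   \code{noise_cv}, \code{drift_per_replicate}, \code{inner_filter}
#' @param seed integer seed controlling scores and noise
#' @return list with \code{cube} (masked \code{eem_cube}) and
#'   \code{truth} (class \code{synthetic_truth}: true scores, unit-norm
#'   true loadings, viability, noise parameters, seed)
#' @export
generate_cube <- function(config = list(), seed = NULL) {
  cfg <- utils::modifyList(
    list(grid = NULL, prototypes = NULL, design = NULL,
         viability_table = default_viability_table(),
         trend_params = default_trend_params(),
         noise_rms_frac = 0.001, noise_cv = 0.03,
         drift_per_replicate = 0, inner_filter = FALSE),
    config)
  grid <- if (is.null(cfg$grid)) build_acquisition_grid() else cfg$grid
  protos <- if (is.null(cfg$prototypes)) default_prototypes(grid)
            else cfg$prototypes
  design <- if (is.null(cfg$design)) generate_design() else cfg$design
  viability <- viability_map(design$cell_line, design$dose_uM,
                             table = cfg$viability_table)
  B <- vapply(protos, `[[`, numeric(length(grid$em_wavelengths)),
              "em_profile")
  C <- vapply(protos, `[[`, numeric(length(grid$ex_wavelengths)),
              "ex_profile")
  A <- generate_scores(design, viability,
                       trend_params = cfg$trend_params,
                       noise_cv = cfg$noise_cv,
                       drift_per_replicate = cfg$drift_per_replicate,
                       inner_filter = cfg$inner_filter,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  I <- nrow(design); J <- nrow(B); K <- nrow(C)
  signal <- array(tcrossprod(A, khatri_rao(C, B)), c(I, J, K))
  measured <- rep(grid$measured_mask, each = I)
  noise_sd <- cfg$noise_rms_frac * sqrt(mean(signal[measured]^2))
  noise <- with_seed(if (is.null(seed)) NULL else seed + 2L,
                     array(stats::rnorm(length(signal), 0, noise_sd),
                           dim(signal)))
  data <- signal + noise
  data[!measured] <- NA_real_
  cube <- new_eem_cube(grid, data, design)
  truth <- structure(
    list(scores = A, em_loadings = B, ex_loadings = C,
         prototypes = protos, viability = viability,
         noise_sd = noise_sd, noise_rms_frac = cfg$noise_rms_frac,
         seed = seed),
    class = "synthetic_truth")
  list(cube = cube, truth = truth)
}

#' Simulate an MTT viability reference table
#'
#' Draws \code{n_replicates} absorbance-ratio replicates per (cell line,
#' dose) group around the ground-truth viability with the given
#' coefficient of variation, then normalizes each cell line so its
#' control group mean is exactly 100\% (the MTT ratio definition).
#'
#' @param design a design data.frame (the distinct (cell_line, dose)
#'   pairs define the groups)
#' @param viability_table lookup table as in \code{\link{viability_map}}
#' @param n_replicates MTT replicates per group (default 5)
#' @param cv coefficient of variation of the replicates (default 0.05)
#' @param seed integer seed
#' @return list with \code{replicates} (long data.frame: cell_line,
#'   dose_uM, replicate, viability_pct) and \code{summary} (per group:
#'   mean, sd, n)
#' @export
mtt_reference <- function(design,
                          viability_table = default_viability_table(),
                          n_replicates = 5, cv = 0.05, seed = NULL) {
  groups <- unique(design[, c("cell_line", "dose_uM")])
  groups <- groups[order(groups$cell_line, groups$dose_uM), ]
  v <- viability_map(groups$cell_line, groups$dose_uM,
                     table = viability_table)
  reps <- with_seed(seed, {
    vals <- rep(v, each = n_replicates) *
      (1 + cv * stats::rnorm(nrow(groups) * n_replicates))
    data.frame(cell_line = rep(groups$cell_line, each = n_replicates),
               dose_uM = rep(groups$dose_uM, each = n_replicates),
               replicate = rep(seq_len(n_replicates), nrow(groups)),
               viability_pct = vals)
  })
  # self-normalize: control mean defines 100% within each cell line
  for (cl in unique(reps$cell_line)) {
    ctrl <- reps$cell_line == cl & reps$dose_uM == 0
    reps$viability_pct[reps$cell_line == cl] <-
      reps$viability_pct[reps$cell_line == cl] *
      100 / mean(reps$viability_pct[ctrl])
  }
  agg <- stats::aggregate(viability_pct ~ cell_line + dose_uM, reps,
                          function(z) c(mean = mean(z), sd = stats::sd(z)))
  summary <- data.frame(agg[c("cell_line", "dose_uM")],
                        mean = agg$viability_pct[, "mean"],
                        sd = agg$viability_pct[, "sd"],
                        n = n_replicates)
  summary <- summary[order(summary$cell_line, summary$dose_uM), ]
  rownames(summary) <- NULL
  list(replicates = reps, summary = summary)
}
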