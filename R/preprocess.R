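#' Fill the non-physical region of a masked EEM
#'
#' Completes the triangular unmeasured region of one EEM sample: in each
#' excitation column, cells at or below the first-order Rayleigh line
#' (emission <= excitation) are set to zero, and the unmeasured band
#' between the Rayleigh line and the first measured emission point is
#' linearly interpolated along the emission axis between an anchor value
#' of 0 on the Rayleigh line and the first measured intensity. Measured
#' cells are never altered, so the output is complete and non-negative
#' whenever the measured values are.
#'
#' @param sample an \code{eem_sample} with intensities wherever the grid
#'   mask is \code{TRUE}
#' @param rayleigh_halfwidth half-width (nm) of the scatter band zeroed
#'   above the Rayleigh line before the ramp starts; 0 anchors the ramp
#'   directly on the line
#' @param clip_negative if \code{TRUE}, negative measured intensities are
#'   clipped to zero (a warning is always emitted when they occur)
#' @return the sample with a complete intensity matrix; the logical
#'   matrix of imputed cells is attached as attribute \code{"imputed"}
#' @export
fill_nonphysical_region <- function(sample, rayleigh_halfwidth = 0,
                                    clip_negative = FALSE) {
  stopifnot(inherits(sample, "eem_sample"), rayleigh_halfwidth >= 0)
  g <- sample$grid
  x <- sample$intensity
  mask <- g$measured_mask
  if (anyNA(x[mask])) stop("missing intensity inside the measured region")
  if (any(x[mask] < 0, na.rm = TRUE)) {
    warning("negative measured intensities present",
            if (clip_negative) "; clipping to 0")
    if (clip_negative) x[mask & x < 0] <- 0
  }
  em <- g$em_wavelengths
  for (k in seq_along(g$ex_wavelengths)) {
    col_mask <- mask[, k]
    if (all(col_mask)) next
    ex_k <- g$ex_wavelengths[k]
    zero_to <- ex_k + rayleigh_halfwidth
    m_idx <- which(col_mask)[1]       # first measured emission point
    anchor_val <- x[m_idx, k]
    fill <- which(!col_mask)
    below <- fill[em[fill] <= zero_to]
    ramp <- fill[em[fill] > zero_to]
    x[below, k] <- 0
    if (length(ramp)) {
      frac <- (em[ramp] - zero_to) / (em[m_idx] - zero_to)
      x[ramp, k] <- frac * anchor_val
    }
  }
  out <- sample
  out$intensity <- x
  attr(out, "imputed") <- !mask
  out
}

#' Preprocess every sample of a masked EEM cube
#'
#' Applies \code{\link{fill_nonphysical_region}} to each sample so the
#' cube is complete (no missing entries) and suitable for trilinear
#' decomposition. The set of imputed cells, identical across samples, is
#' recorded in the cube's provenance.
#'
#' @param cube an \code{eem_cube} straight from acquisition or simulation
#' @inheritParams fill_nonphysical_region
#' @return the completed \code{eem_cube} with \code{preprocessed = TRUE}
#'   and \code{provenance$imputed_mask} set
#' @export
preprocess_cube <- function(cube, rayleigh_halfwidth = 0,
                            clip_negative = FALSE) {
  stopifnot(inherits(cube, "eem_cube"))
  g <- cube$grid
  data <- cube$data
  measured <- rep(g$measured_mask, each = dim(data)[1])
  n_neg <- sum(data[measured] < 0, na.rm = TRUE)
  if (n_neg > 0)
    warning(n_neg, " negative measured intensities in the cube",
            if (clip_negative) "; clipping to 0")
  for (i in seq_len(dim(data)[1])) {
    s <- structure(list(grid = g, intensity = data[i, , ],
                        meta = as.list(cube$samples[i, ])),
                   class = "eem_sample")
    data[i, , ] <- suppressWarnings(fill_nonphysical_region(
      s, rayleigh_halfwidth = rayleigh_halfwidth,
      clip_negative = clip_negative))$intensity
  }
  new_eem_cube(g, data, cube$samples, preprocessed = TRUE,
               provenance = list(
                 imputed_mask = !g$measured_mask,
                 rayleigh_halfwidth = rayleigh_halfwidth,
                 clip_negative = clip_negative))
}
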