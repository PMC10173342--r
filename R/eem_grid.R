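#' Build an EEM acquisition wavelength grid
#'
#' Constructs the emission/excitation wavelength grid and the boolean
#' measured-region mask implied by a scanning fluorescence acquisition
#' protocol in which each emission spectrum starts a fixed gap above its
#' excitation wavelength (to skip first-order Rayleigh scatter), except
#' that short excitation wavelengths are recorded from a fixed emission
#' floor. The defaults reproduce a 71 emission x 26 excitation plate-reader
#' protocol: excitation 250-500 nm in 10 nm steps, emission up to 650 nm in
#' 5 nm steps, recorded from \code{ex + 20} nm for \code{ex >= 290} nm and
#' from 300 nm otherwise.
#'
#' @param ex_start,ex_end first and last excitation wavelength (nm)
#' @param ex_step excitation step (nm)
#' @param em_max last emission wavelength (nm)
#' @param em_step emission step (nm)
#' @param gap emission offset above the excitation wavelength at which
#'   recording starts for long-wavelength excitation columns (nm)
#' @param em_floor emission wavelength from which short-wavelength
#'   excitation columns are recorded (nm)
#' @param floor_threshold excitation wavelength below which the
#'   \code{em_floor} rule applies (nm)
#' @return an object of class \code{eem_grid}: a list with integer vectors
#'   \code{em_wavelengths}, \code{ex_wavelengths} and the logical matrix
#'   \code{measured_mask} (emission rows x excitation columns, \code{TRUE}
#'   where the protocol records intensity)
#' @examples
#' g <- build_acquisition_grid()
#' dim(g$measured_mask)  # 71 x 26
#' @export
build_acquisition_grid <- function(ex_start = 250, ex_end = 500, ex_step = 10,
                                   em_max = 650, em_step = 5,
                                   gap = 20, em_floor = 300,
                                   floor_threshold = 290) {
  stopifnot(ex_start <= ex_end, ex_step > 0, em_step > 0, em_max > em_floor)
  on_lattice <- function(x, step) abs(x / step - round(x / step)) < 1e-9
  if (!on_lattice(ex_end - ex_start, ex_step))
    stop("excitation range (", ex_start, "-", ex_end,
         ") is not a whole number of ex_step = ", ex_step, " nm steps")
  ex <- seq(ex_start, ex_end, by = ex_step)
  start_em <- ifelse(ex < floor_threshold, em_floor, ex + gap)
  bad <- !on_lattice(em_max - start_em, em_step)
  if (any(bad))
    stop("emission start for excitation column(s) ",
         paste(ex[bad], collapse = ", "),
         " nm does not fall on the em_step = ", em_step, " nm lattice")
  em <- seq(min(start_em), em_max, by = em_step)
  mask <- outer(em, start_em, `>=`)
  structure(
    list(em_wavelengths = as.integer(round(em)),
         ex_wavelengths = as.integer(round(ex)),
         measured_mask = mask,
         params = list(ex_start = ex_start, ex_end = ex_end,
                       ex_step = ex_step, em_max = em_max, em_step = em_step,
                       gap = gap, em_floor = em_floor,
                       floor_threshold = floor_threshold)),
    class = "eem_grid")
}

#' @export
print.eem_grid <- function(x, ...) {
  cat("EEM acquisition grid:",
      length(x$em_wavelengths), "emission x",
      length(x$ex_wavelengths), "excitation points\n")
  cat("  emission  ", min(x$em_wavelengths), "-", max(x$em_wavelengths),
      "nm, step", x$params$em_step, "nm\n")
  cat("  excitation", min(x$ex_wavelengths), "-", max(x$ex_wavelengths),
      "nm, step", x$params$ex_step, "nm\n")
  cat("  unmeasured cells:", sum(!x$measured_mask), "of",
      length(x$measured_mask), "\n")
  invisible(x)
}

grids_equal <- function(a, b) {
  identical(a$em_wavelengths, b$em_wavelengths) &&
    identical(a$ex_wavelengths, b$ex_wavelengths) &&
    identical(unname(a$measured_mask), unname(b$measured_mask))
}

#' Create one EEM sample
#'
#' Wraps an intensity matrix on a grid together with sample metadata.
#' Before preprocessing, intensities must be present (non-\code{NA})
#' exactly where \code{grid$measured_mask} is \code{TRUE}.
#'
#' @param grid an \code{eem_grid}
#' @param intensity numeric matrix (emission rows x excitation columns)
#' @param cell_line cell line label (e.g. \code{"A375"})
#' @param dose dose in uM; 0 denotes the untreated control
#' @param replicate replicate index
#' @return an object of class \code{eem_sample}
#' @export
eem_sample <- function(grid, intensity, cell_line, dose, replicate) {
  stopifnot(inherits(grid, "eem_grid"))
  intensity <- as.matrix(intensity)
  if (!all(dim(intensity) == dim(grid$measured_mask)))
    stop("intensity matrix must be ",
         nrow(grid$measured_mask), " x ", ncol(grid$measured_mask))
  if (anyNA(intensity[grid$measured_mask]))
    stop("missing intensity inside the measured region")
  structure(
    list(grid = grid, intensity = intensity,
         meta = list(cell_line = as.character(cell_line),
                     dose = as.numeric(dose),
                     replicate = as.integer(replicate))),
    class = "eem_sample")
}
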