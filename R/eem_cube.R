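#' Assemble EEM samples into a three-way cube
#'
#' Stacks per-sample EEM matrices into an I x J x K array (samples x
#' emission x excitation) with an aligned metadata table, the container
#' all downstream trilinear modelling operates on.
#'
#' @param samples list of \code{eem_sample} objects sharing one grid
#' @return an object of class \code{eem_cube}: list with \code{grid},
#'   \code{data} (3-way array) and \code{samples} (data.frame with columns
#'   \code{sample_id}, \code{cell_line}, \code{dose_uM}, \code{replicate})
#' @export
assemble_cube <- function(samples) {
  if (length(samples) == 0) stop("cannot assemble a cube from zero samples")
  stopifnot(all(vapply(samples, inherits, logical(1), "eem_sample")))
  grid <- samples[[1]]$grid
  ok <- vapply(samples, function(s) grids_equal(s$grid, grid), logical(1))
  if (!all(ok))
    stop("samples ", paste(which(!ok), collapse = ", "),
         " are on a different wavelength grid")
  J <- length(grid$em_wavelengths)
  K <- length(grid$ex_wavelengths)
  I <- length(samples)
  data <- array(NA_real_, dim = c(I, J, K))
  meta <- data.frame(
    sample_id = character(I), cell_line = character(I),
    dose_uM = numeric(I), replicate = integer(I),
    stringsAsFactors = FALSE)
  for (i in seq_len(I)) {
    s <- samples[[i]]
    data[i, , ] <- s$intensity
    meta$cell_line[i] <- s$meta$cell_line
    meta$dose_uM[i] <- s$meta$dose
    meta$replicate[i] <- s$meta$replicate
  }
  meta$sample_id <- sprintf("%s_d%04d_r%02d", meta$cell_line,
                            as.integer(meta$dose_uM), meta$replicate)
  if (anyDuplicated(meta[, c("cell_line", "dose_uM", "replicate")]))
    warning("duplicate (cell_line, dose, replicate) triples in metadata")
  new_eem_cube(grid, data, meta)
}

new_eem_cube <- function(grid, data, samples, preprocessed = FALSE,
                         provenance = NULL) {
  stopifnot(dim(data)[1] == nrow(samples),
            dim(data)[2] == length(grid$em_wavelengths),
            dim(data)[3] == length(grid$ex_wavelengths))
  structure(list(grid = grid, data = data, samples = samples,
                 preprocessed = preprocessed, provenance = provenance),
            class = "eem_cube")
}

#' @export
print.eem_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("EEM cube:", d[1], "samples x", d[2], "emission x", d[3],
      "excitation\n")
  cat("  cell lines:", paste(unique(x$samples$cell_line), collapse = ", "),
      "\n")
  cat("  preprocessed:", x$preprocessed,
      if (anyNA(x$data)) " (contains unmeasured cells)" else "", "\n")
  invisible(x)
}

#' @export
dim.eem_cube <- function(x) dim(x$data)

#' Write an EEM cube to disk
#'
#' Serializes a cube as one CSV matrix per sample (first column emission
#' wavelengths, first row excitation wavelengths, empty fields for
#' unmeasured cells) plus a JSON manifest carrying the grid parameters,
#' the metadata table and the per-sample file names. \code{read_cube}
#' inverts the operation; the pair round-trips a cube to machine
#' precision.
#'
#' @param cube an \code{eem_cube}
#' @param path directory to write into (created if absent)
#' @return invisibly, the manifest path
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "eem_cube"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- cube$grid
  files <- sprintf("sample_%03d.csv", seq_len(nrow(cube$samples)))
  for (i in seq_along(files)) {
    m <- cube$data[i, , ]
    tab <- cbind(g$em_wavelengths, m)
    colnames(tab) <- c("em_nm", g$ex_wavelengths)
    utils::write.table(
      tab, file.path(path, files[i]), sep = ",", na = "",
      row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  manifest <- list(
    format = "eemviva-cube", version = 1L,
    grid = g$params,
    em_wavelengths = g$em_wavelengths,
    ex_wavelengths = g$ex_wavelengths,
    preprocessed = cube$preprocessed,
    files = files,
    samples = cube$samples)
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  utils::write.csv(cube$samples[, c("sample_id", "cell_line", "dose_uM",
                                    "replicate")],
                   file.path(path, "samples.csv"), row.names = FALSE)
  invisible(mf)
}

#' Read an EEM cube written by \code{write_cube}
#'
#' @param path the directory (or its \code{manifest.json}) written by
#'   \code{\link{write_cube}}
#' @return an \code{eem_cube}
#' @export
read_cube <- function(path) {
  mf <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(mf)) stop("no manifest.json at ", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(man$format, "eemviva-cube"))
    stop("not an eemviva cube manifest: ", mf)
  grid <- do.call(build_acquisition_grid, as.list(man$grid))
  if (!identical(grid$em_wavelengths, as.integer(man$em_wavelengths)) ||
      !identical(grid$ex_wavelengths, as.integer(man$ex_wavelengths)))
    stop("manifest wavelength axes disagree with its grid parameters")
  samples <- as.data.frame(man$samples, stringsAsFactors = FALSE)
  J <- length(grid$em_wavelengths); K <- length(grid$ex_wavelengths)
  I <- nrow(samples)
  if (length(man$files) != I)
    stop("manifest lists ", length(man$files), " files for ", I,
         " metadata rows")
  dir <- dirname(mf)
  data <- array(NA_real_, dim = c(I, J, K))
  for (i in seq_len(I)) {
    tab <- utils::read.csv(file.path(dir, man$files[i]),
                           check.names = FALSE)
    if (nrow(tab) != J || ncol(tab) != K + 1)
      stop("sample file ", man$files[i], " is ", nrow(tab), " x ",
           ncol(tab) - 1, ", expected ", J, " x ", K)
    if (!isTRUE(all.equal(as.numeric(tab[[1]]),
                          as.numeric(grid$em_wavelengths))) ||
        !isTRUE(all.equal(as.numeric(colnames(tab)[-1]),
                          as.numeric(grid$ex_wavelengths))))
      stop("wavelength axes in ", man$files[i],
           " disagree with the manifest grid")
    data[i, , ] <- as.matrix(tab[, -1, drop = FALSE])
  }
  new_eem_cube(grid, data, samples,
               preprocessed = isTRUE(man$preprocessed))
}

#' Extract a subset of samples from a cube
#'
#' @param cube an \code{eem_cube}
#' @param idx integer or logical sample index
#' @return an \code{eem_cube} with the selected samples
#' @export
subset_cube <- function(cube, idx) {
  new_eem_cube(cube$grid,
               cube$data[idx, , , drop = FALSE],
               cube$samples[idx, , drop = FALSE],
               preprocessed = cube$preprocessed,
               provenance = cube$provenance)
}
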