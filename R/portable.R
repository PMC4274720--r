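#' Portable single-file container for a set of spectra
#'
#' Stores any number of spectra sharing one grid in a single HDF5 file with
#' datasets `intensities` (`n x n_f1 x n_f2`, 64-bit float — synthetic
#' ground truth is never degraded by integer quantization), `ppm_f1`,
#' `ppm_f2`, `sample_ids` and `scale_exponents`. Round trips are lossless.
#'
#' @param spectra non-empty list of [hsqc_spectrum()] objects on one grid.
#' @param path output file path (overwritten if present).
#' @export
write_portable <- function(spectra, path) {
  if (length(spectra) == 0L)
    stop("refusing to write an empty container: no spectra given", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, TRUE, "HSQCSpectrum")))
  g <- spectra[[1]]$grid
  bad <- vapply(spectra, function(s) !grids_equal(s$grid, g), TRUE)
  if (any(bad))
    stop(sprintf("spectra are not on a common grid; offending sample_ids: %s",
                 paste(vapply(spectra[bad], `[[`, "", "sample_id"),
                       collapse = ", ")), call. = FALSE)
  n <- length(spectra)
  arr <- array(0, dim = c(n, g$n_f1, g$n_f2))
  for (i in seq_len(n)) arr[i, , ] <- spectra[[i]]$intensities

  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(arr, path, "intensities")
  rhdf5::h5write(g$ppm_f1, path, "ppm_f1")
  rhdf5::h5write(g$ppm_f2, path, "ppm_f2")
  rhdf5::h5write(vapply(spectra, `[[`, "", "sample_id"), path, "sample_ids")
  rhdf5::h5write(vapply(spectra, function(s) s$scale_exponent, 0L),
                 path, "scale_exponents")
  invisible(path)
}

#' @rdname write_portable
#' @return `read_portable` returns the list of spectra in stored order.
#' @export
read_portable <- function(path) {
  if (!file.exists(path))
    stop_class("hsqccor_missing_file", "missing container file: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  arr <- rhdf5::h5read(path, "intensities")
  grid <- spectrum_grid(ppm_f2 = as.numeric(rhdf5::h5read(path, "ppm_f2")),
                        ppm_f1 = as.numeric(rhdf5::h5read(path, "ppm_f1")))
  ids <- as.character(rhdf5::h5read(path, "sample_ids"))
  exps <- as.integer(rhdf5::h5read(path, "scale_exponents"))
  lapply(seq_along(ids), function(i)
    hsqc_spectrum(grid, matrix(arr[i, , ], grid$n_f1, grid$n_f2),
                  sample_id = ids[i], scale_exponent = exps[i]))
}
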