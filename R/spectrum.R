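#' One processed 2D HSQC spectrum
#'
#' Binds an intensity matrix to a [spectrum_grid()]. Intensities are stored
#' as an `n_f1 x n_f2` real matrix (rows = 13C, columns = 1H), in arbitrary
#' units. `scale_exponent` records the power-of-two intensity scaling
#' (Bruker `NC_proc`) applied when the spectrum was read; intensities here
#' are always already multiplied out.
#'
#' @param grid a [spectrum_grid()].
#' @param intensities numeric matrix of size `n_f1 x n_f2`, all finite.
#' @param sample_id text label for the sample.
#' @param scale_exponent integer power-of-two scaling from the source
#'   metadata (informational; default 0).
#' @return An object of class `HSQCSpectrum`.
#' @export
hsqc_spectrum <- function(grid, intensities, sample_id = "sample",
                          scale_exponent = 0L) {
  stopifnot(inherits(grid, "SpectrumGrid"))
  if (!is.matrix(intensities) ||
      nrow(intensities) != grid$n_f1 || ncol(intensities) != grid$n_f2)
    stop(sprintf("intensities must be a %d x %d matrix (n_f1 x n_f2)",
                 grid$n_f1, grid$n_f2), call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities contain non-finite values", call. = FALSE)
  structure(
    list(grid = grid, intensities = intensities,
         sample_id = as.character(sample_id),
         scale_exponent = as.integer(scale_exponent)),
    class = "HSQCSpectrum")
}

#' @export
print.HSQCSpectrum <- function(x, ...) {
  cat(sprintf("HSQCSpectrum '%s': %d x %d points (F1 x F2), max |I| = %.4g\n",
              x$sample_id, x$grid$n_f1, x$grid$n_f2, max(abs(x$intensities))))
  if (isTRUE(attr(x, "uncalibrated")))
    cat("  [flagged: uncalibrated]\n")
  invisible(x)
}

# robust noise-floor estimate used by calibration sanity checks
noise_floor <- function(spectrum, multiplier = 5) {
  multiplier * stats::mad(spectrum$intensities)
}
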