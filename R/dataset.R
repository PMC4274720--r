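#' Calibrate a spectrum to a chemical-shift reference peak
#'
#' Locates the maximum-intensity point inside a search window (by default
#' around the TSP resonance) and shifts both ppm axes, in whole grid
#' points, so that this maximum sits as close as possible to
#' `reference_ppm`. Intensities are never interpolated: sub-pixel
#' interpolation would alter the values the correlation is computed from,
#' so calibration works at grid-point granularity.
#'
#' If the window maximum does not rise above the spectrum's robust noise
#' floor (5 x MAD of all intensities) the spectrum is returned unshifted
#' with a warning and an `uncalibrated` attribute set.
#'
#' @param spectrum an [hsqc_spectrum()].
#' @param search_window list with elements `f2` and `f1`, each a ppm range
#'   `c(low, high)` to search; must intersect the grid.
#' @param reference_ppm target position `c(h, c)` in ppm; TSP is (0, 0).
#' @return The calibrated spectrum, on a shifted grid.
#' @export
calibrate_to_reference <- function(spectrum,
                                   search_window = list(f2 = c(-0.3, 0.3),
                                                        f1 = c(-5, 5)),
                                   reference_ppm = c(h = 0, c = 0)) {
  g <- spectrum$grid
  in2 <- which(g$ppm_f2 >= min(search_window$f2) & g$ppm_f2 <= max(search_window$f2))
  in1 <- which(g$ppm_f1 >= min(search_window$f1) & g$ppm_f1 <= max(search_window$f1))
  if (length(in2) == 0L || length(in1) == 0L)
    stop("calibration search window lies outside the grid", call. = FALSE)

  sub <- spectrum$intensities[in1, in2, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  i1 <- in1[k[1]]; i2 <- in2[k[2]]
  if (sub[k] < noise_floor(spectrum)) {
    warning(sprintf(
      "calibration window maximum (%.4g) is below the noise floor; '%s' left uncalibrated",
      sub[k], spectrum$sample_id), call. = FALSE)
    attr(spectrum, "uncalibrated") <- TRUE
    return(spectrum)
  }

  d <- grid_spacing(g)
  shift2 <- round((g$ppm_f2[i2] - reference_ppm[[1]]) / d[["f2"]])
  shift1 <- round((g$ppm_f1[i1] - reference_ppm[[2]]) / d[["f1"]])
  grid2 <- spectrum_grid(ppm_f2 = g$ppm_f2 - shift2 * d[["f2"]],
                         ppm_f1 = g$ppm_f1 - shift1 * d[["f1"]])
  hsqc_spectrum(grid2, spectrum$intensities, spectrum$sample_id,
                spectrum$scale_exponent)
}

#' Total-intensity normalization (optional)
#'
#' Divides every intensity by the sum of positive intensities and rescales
#' by 1e6 for readable magnitudes. This removes global dilution differences
#' between samples; it is optional and off by default in the pipeline,
#' since correlation coefficients are themselves scale-free.
#'
#' @param spectrum an [hsqc_spectrum()].
#' @export
normalize_total_intensity <- function(spectrum) {
  pos <- spectrum$intensities[spectrum$intensities > 0]
  if (length(pos) == 0L || sum(pos) <= 0)
    stop("cannot normalize: spectrum has no positive intensity", call. = FALSE)
  hsqc_spectrum(spectrum$grid, spectrum$intensities / sum(pos) * 1e6,
                spectrum$sample_id, spectrum$scale_exponent)
}

#' Stack spectra into the n x K data matrix
#'
#' Each spectrum becomes one row, flattened in f1-major order (all F2
#' points of the first 13C row, then the second, ...). The returned
#' `SpectralMatrix` carries a coordinate map from every column to its grid
#' indices and chemical shifts, and a keep-mask over all `n_f1 * n_f2`
#' columns (initially all `TRUE`; see [apply_noise_exclusion()]).
#'
#' Spectra must share one grid exactly — a mismatch is an error, never a
#' silent resampling.
#'
#' @param spectra list of at least two [hsqc_spectrum()] objects.
#' @return An object of class `SpectralMatrix` with fields `values`
#'   (n x K_kept), `coordinate_map`, `kept_mask`, `grid`, `sample_ids`,
#'   `noise_threshold`.
#' @export
stack_spectra <- function(spectra) {
  if (length(spectra) < 2L)
    stop("at least 2 spectra are required (correlation is undefined for n < 2)",
         call. = FALSE)
  g <- spectra[[1]]$grid
  for (s in spectra[-1]) {
    if (!grids_equal(s$grid, g)) {
      dif2 <- which(abs(s$grid$ppm_f2 - g$ppm_f2) > 1e-9)
      dif1 <- which(abs(s$grid$ppm_f1 - g$ppm_f1) > 1e-9)
      where <- if (length(dif2)) sprintf("F2 point %d (%.6f vs %.6f ppm)",
                                         dif2[1], s$grid$ppm_f2[dif2[1]], g$ppm_f2[dif2[1]])
               else if (length(dif1)) sprintf("F1 point %d (%.6f vs %.6f ppm)",
                                              dif1[1], s$grid$ppm_f1[dif1[1]], g$ppm_f1[dif1[1]])
               else "grid dimensions"
      stop(sprintf("grid mismatch for sample '%s': first difference at %s",
                   s$sample_id, where), call. = FALSE)
    }
  }
  n <- length(spectra)
  K <- g$n_f1 * g$n_f2
  values <- matrix(0, n, K)
  for (i in seq_len(n)) values[i, ] <- as.vector(t(spectra[[i]]$intensities))
  i_f1 <- rep(seq_len(g$n_f1), each = g$n_f2)
  i_f2 <- rep(seq_len(g$n_f2), times = g$n_f1)
  structure(
    list(values = values,
         coordinate_map = data.frame(
           column = seq_len(K), i_f1 = i_f1, i_f2 = i_f2,
           ppm_c = g$ppm_f1[i_f1], ppm_h = g$ppm_f2[i_f2]),
         kept_mask = rep(TRUE, K),
         grid = g,
         sample_ids = vapply(spectra, `[[`, "", "sample_id"),
         noise_threshold = 0),
    class = "SpectralMatrix")
}

#' Rebuild one spectrum from a row of the data matrix
#'
#' Inverse of [stack_spectra()] for a single row: excluded columns are
#' re-introduced as zeros and the vector reshaped to the grid.
#'
#' @param matrix a `SpectralMatrix`.
#' @param row sample index.
#' @export
unstack_row <- function(matrix, row) {
  g <- matrix$grid
  full <- numeric(g$n_f1 * g$n_f2)
  full[matrix$coordinate_map$column] <- matrix$values[row, ]
  hsqc_spectrum(g, t(base::matrix(full, g$n_f2, g$n_f1)),
                sample_id = matrix$sample_ids[row])
}

#' Advisory noise threshold from the data matrix
#'
#' Returns `multiplier` times the median absolute deviation of all matrix
#' values — a robust noise-scale estimate for sparse spectra, where the
#' bulk of points is baseline noise. Purely advisory: the exclusion step
#' takes an explicit threshold, as in practice the threshold is chosen by
#' inspecting a plotted row vector.
#'
#' @param matrix a `SpectralMatrix`.
#' @param multiplier noise-floor multiple; default 5.
#' @export
suggest_noise_threshold <- function(matrix, multiplier = 5) {
  if (length(matrix$values) == 0L) stop("empty matrix", call. = FALSE)
  thr <- multiplier * stats::mad(matrix$values)
  if (thr == 0 && multiplier > 0)
    warning("MAD of the data is 0 (near-constant values); set a threshold manually",
            call. = FALSE)
  thr
}

#' Noise exclusion: drop columns below threshold in every spectrum
#'
#' A column (grid point) is removed only when all `n` values in it are
#' below the threshold — a point is kept as soon as any sample shows
#' signal there. Comparison uses the absolute value by default, because
#' processed spectra can carry negative excursions; set `signed = TRUE`
#' for the one-sided rule. Re-exclusion composes: applying a higher
#' threshold to an already-excluded matrix removes further columns and
#' never re-admits any.
#'
#' @param matrix a `SpectralMatrix`.
#' @param threshold intensity threshold, `>= 0`.
#' @param signed if `TRUE`, compare raw values instead of magnitudes.
#' @export
apply_noise_exclusion <- function(matrix, threshold, signed = FALSE) {
  stopifnot(threshold >= 0)
  cmp <- if (signed) matrix$values else abs(matrix$values)
  keep <- apply(cmp >= threshold, 2L, any)
  if (!any(keep))
    stop("no signal columns remain at this threshold", call. = FALSE)
  mask <- matrix$kept_mask
  mask[matrix$coordinate_map$column[!keep]] <- FALSE
  structure(
    list(values = matrix$values[, keep, drop = FALSE],
         coordinate_map = matrix$coordinate_map[keep, , drop = FALSE],
         kept_mask = mask,
         grid = matrix$grid,
         sample_ids = matrix$sample_ids,
         noise_threshold = max(threshold, matrix$noise_threshold)),
    class = "SpectralMatrix")
}

#' @export
print.SpectralMatrix <- function(x, ...) {
  cat(sprintf("SpectralMatrix: %d spectra x %d kept columns (of %d; threshold %.4g)\n",
              nrow(x$values), ncol(x$values), length(x$kept_mask),
              x$noise_threshold))
  invisible(x)
}
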