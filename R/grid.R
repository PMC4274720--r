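#' Spectrum grid: shared chemical-shift axes of a 2D HSQC dataset
#'
#' A `SpectrumGrid` holds the ppm axes that every spectrum and correlation
#' plot in an analysis lives on: the direct (F2, 1H) axis and the indirect
#' (F1, 13C) axis. Both axes run from low field (high ppm) to high field
#' (low ppm), i.e. they are strictly decreasing, and must be uniformly
#' spaced.
#'
#' @param ppm_f2 numeric vector of 1H chemical shifts (ppm), strictly
#'   decreasing, uniformly spaced.
#' @param ppm_f1 numeric vector of 13C chemical shifts (ppm), strictly
#'   decreasing, uniformly spaced.
#' @return An object of class `SpectrumGrid` with fields `ppm_f2`, `ppm_f1`,
#'   `n_f2`, `n_f1`.
#' @export
spectrum_grid <- function(ppm_f2, ppm_f1) {
  check_axis(ppm_f2, "ppm_f2")
  check_axis(ppm_f1, "ppm_f1")
  structure(
    list(ppm_f2 = as.numeric(ppm_f2), ppm_f1 = as.numeric(ppm_f1),
         n_f2 = length(ppm_f2), n_f1 = length(ppm_f1)),
    class = "SpectrumGrid")
}

# uniform, strictly decreasing axis; relative spacing tolerance 1e-6
check_axis <- function(x, name) {
  if (length(x) < 2L || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("axis '%s' must be a finite numeric vector of length >= 2", name),
         call. = FALSE)
  d <- diff(x)
  if (any(d >= 0))
    stop(sprintf("axis '%s' must be strictly decreasing (high field last)", name),
         call. = FALSE)
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
    stop(sprintf("axis '%s' is not uniformly spaced", name), call. = FALSE)
  invisible(x)
}

#' Build a grid from sweep width and left-edge offset
#'
#' Axis values follow the processed-Bruker convention: the first point sits
#' at the left edge (`offset`, the most downfield shift) and point `i`
#' (0-based) sits at `offset - i * sw_ppm / n`.
#'
#' @param n_f2,n_f1 number of points in the direct (1H) and indirect (13C)
#'   dimension.
#' @param offset_f2,offset_f1 left-edge chemical shift (ppm) per dimension.
#' @param sw_f2,sw_f1 spectral width (ppm) per dimension.
#' @return A [spectrum_grid()].
#' @export
grid_from_params <- function(n_f2, n_f1, offset_f2, sw_f2, offset_f1, sw_f1) {
  spectrum_grid(
    ppm_f2 = offset_f2 - (seq_len(n_f2) - 1) * sw_f2 / n_f2,
    ppm_f1 = offset_f1 - (seq_len(n_f1) - 1) * sw_f1 / n_f1)
}

#' Default urine-HSQC grid
#'
#' 1024 x 512 points (F2 x F1) covering 16 ppm of 1H centred at 4.7 ppm and
#' 165 ppm of 13C centred at 75 ppm, the standard acquisition scheme for
#' urine HSQC profiling. The left edges are therefore 12.7 ppm (1H) and
#' 157.5 ppm (13C); TSP at (0, 0) ppm lies inside the grid.
#'
#' @param n_f2,n_f1 grid size; reduce (e.g. 512 x 256) for faster synthetic
#'   studies over the same spectral window.
#' @return A [spectrum_grid()].
#' @export
default_grid <- function(n_f2 = 1024L, n_f1 = 512L) {
  grid_from_params(n_f2, n_f1,
                   offset_f2 = 4.7 + 16 / 2, sw_f2 = 16,
                   offset_f1 = 75 + 165 / 2, sw_f1 = 165)
}

grid_spacing <- function(grid) {
  c(f2 = grid$ppm_f2[1] - grid$ppm_f2[2],
    f1 = grid$ppm_f1[1] - grid$ppm_f1[2])
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_f2 == b$n_f2 && a$n_f1 == b$n_f1 &&
    max(abs(a$ppm_f2 - b$ppm_f2)) <= tol &&
    max(abs(a$ppm_f1 - b$ppm_f1)) <= tol
}

# nearest grid indices for a (1H, 13C) ppm position; NA outside the axis range
nearest_index <- function(axis, ppm) {
  d <- axis[1] - axis[2]
  i <- round((axis[1] - ppm) / d) + 1
  ifelse(ppm > axis[1] + d / 2 | ppm < axis[length(axis)] - d / 2, NA_integer_,
         as.integer(pmin(pmax(i, 1), length(axis))))
}

#' @export
print.SpectrumGrid <- function(x, ...) {
  cat(sprintf("SpectrumGrid: %d x %d points (F2 x F1)\n", x$n_f2, x$n_f1))
  cat(sprintf("  1H  (F2): %.4f .. %.4f ppm\n", x$ppm_f2[1], x$ppm_f2[x$n_f2]))
  cat(sprintf("  13C (F1): %.3f .. %.3f ppm\n", x$ppm_f1[1], x$ppm_f1[x$n_f1]))
  invisible(x)
}
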