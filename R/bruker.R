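#' @title Processed Bruker 2D data: reading and writing
#' @description
#' Readers and writers for the processed-Bruker dialect used to exchange
#' 2D HSQC spectra with Topspin: a `2rr` file of 32-bit integers plus
#' `procs` / `proc2s` ASCII parameter files (JCAMP-DX style
#' `##$KEY= value` lines). Honoured keys, per dimension: `SI` (points),
#' `SF` (spectrometer frequency, MHz), `OFFSET` (left-edge ppm), `SW_p`
#' (spectral width, Hz), `XDIM` (submatrix size), `BYTORDP` (byte order,
#' 0 = little, 1 = big) and `NC_proc` (power-of-two intensity exponent).
#' `procs` describes F2 (1H), `proc2s` describes F1 (13C).
#'
#' The `2rr` intensity file may be tiled (submatrix storage, `XDIM < SI`)
#' or untiled (`XDIM = SI`); both are read. Written files are always
#' untiled and little-endian.
#' @name bruker_io
NULL

stop_class <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

# parse "##$KEY= value" lines of a procs-style file into a named list
parse_procs <- function(path) {
  if (!file.exists(path))
    stop_class("hsqccor_missing_file", "missing parameter file: %s", path)
  lines <- readLines(path, warn = FALSE)
  m <- regmatches(lines, regexec("^##\\$([A-Za-z_0-9]+)=\\s*(.*)$", lines))
  m <- Filter(function(x) length(x) == 3L, m)
  vals <- lapply(m, function(x) {
    v <- suppressWarnings(as.numeric(x[3]))
    if (is.na(v)) x[3] else v
  })
  stats::setNames(vals, vapply(m, `[`, "", 2L))
}

require_key <- function(params, key, path) {
  if (is.null(params[[key]]))
    stop_class("hsqccor_missing_parameter",
               "parameter '%s' missing from %s", key, path)
  params[[key]]
}

# ppm axis from processed parameters: point i (0-based) at
# OFFSET - i * (SW_p / SF) / SI
axis_from_procs <- function(si, sf, offset, sw_hz) {
  offset - (seq_len(si) - 1) * (sw_hz / sf) / si
}

# de-tiling: map 0-based linear file positions to (row, col) of the
# n1 x n2 matrix, for submatrix sizes xd1 x xd2
detile_index <- function(n1, n2, xd1, xd2) {
  p <- seq_len(n1 * n2) - 1L
  tsz <- xd1 * xd2
  tiles_per_row <- n2 %/% xd2
  tile <- p %/% tsz
  within <- p %% tsz
  i1 <- (tile %/% tiles_per_row) * xd1 + within %/% xd2
  i2 <- (tile %% tiles_per_row) * xd2 + within %% xd2
  cbind(i1 + 1L, i2 + 1L)
}

#' Read a processed Bruker 2D spectrum
#'
#' @param directory_path directory containing `2rr`, `procs` and `proc2s`.
#' @param sample_id label for the returned spectrum; defaults to the
#'   directory name.
#' @return An [hsqc_spectrum()]; intensities are the stored integers times
#'   `2^NC_proc`, with `NC_proc` recorded as `scale_exponent`.
#' @export
read_bruker_processed <- function(directory_path,
                                  sample_id = basename(directory_path)) {
  f2rr <- file.path(directory_path, "2rr")
  if (!file.exists(f2rr))
    stop_class("hsqccor_missing_file", "missing intensity file: %s", f2rr)
  procs <- parse_procs(file.path(directory_path, "procs"))
  proc2s <- parse_procs(file.path(directory_path, "proc2s"))

  get <- function(p, key, path) require_key(p, key, path)
  pp <- file.path(directory_path, "procs")
  p2 <- file.path(directory_path, "proc2s")
  si2 <- as.integer(get(procs, "SI", pp));  si1 <- as.integer(get(proc2s, "SI", p2))
  sf2 <- get(procs, "SF", pp);              sf1 <- get(proc2s, "SF", p2)
  of2 <- get(procs, "OFFSET", pp);          of1 <- get(proc2s, "OFFSET", p2)
  sw2 <- get(procs, "SW_p", pp);            sw1 <- get(proc2s, "SW_p", p2)
  xd2 <- as.integer(get(procs, "XDIM", pp)); xd1 <- as.integer(get(proc2s, "XDIM", p2))
  bo  <- get(procs, "BYTORDP", pp)
  ncp <- as.integer(get(procs, "NC_proc", pp))

  nbytes <- file.size(f2rr)
  if (nbytes != 4 * si1 * si2)
    stop_class("hsqccor_corrupt_data",
               "2rr has %d bytes but SI parameters imply %d (SI2=%d, SI1=%d)",
               nbytes, 4 * si1 * si2, si2, si1)
  endian <- if (bo == 0) "little" else "big"
  raw <- readBin(f2rr, "integer", n = si1 * si2, size = 4L, endian = endian)

  mat <- matrix(0, si1, si2)
  if (xd1 == si1 && xd2 == si2) {
    mat <- matrix(raw, si1, si2, byrow = TRUE)
  } else {
    if (si1 %% xd1 != 0 || si2 %% xd2 != 0)
      stop_class("hsqccor_corrupt_data",
                 "XDIM (%d, %d) does not divide SI (%d, %d)", xd2, xd1, si2, si1)
    mat[detile_index(si1, si2, xd1, xd2)] <- raw
  }

  # SCALE is this dialect's own key (written by write_bruker_processed so
  # real-valued data survive integer storage); absent in Topspin output
  scale <- procs[["SCALE"]] %||% 1
  grid <- spectrum_grid(ppm_f2 = axis_from_procs(si2, sf2, of2, sw2),
                        ppm_f1 = axis_from_procs(si1, sf1, of1, sw1))
  hsqc_spectrum(grid, mat * 2^ncp / scale, sample_id = sample_id,
                scale_exponent = ncp)
}

write_procs_file <- function(path, si, sf, offset, sw_hz, xdim, scale = NULL) {
  writeLines(c(
    "##TITLE= processed parameters",
    sprintf("##$SI= %d", si),
    sprintf("##$SF= %.8f", sf),
    sprintf("##$OFFSET= %.10f", offset),
    sprintf("##$SW_p= %.10f", sw_hz),
    sprintf("##$XDIM= %d", xdim),
    "##$BYTORDP= 0",
    "##$NC_proc= 0",
    if (!is.null(scale)) sprintf("##$SCALE= %.10g", scale),
    "##END="), path)
}

#' Write a spectrum (or correlation plot) as processed Bruker data
#'
#' Writes an untiled (`XDIM = SI`) little-endian `2rr` with minimal
#' `procs` / `proc2s`, sufficient for [read_bruker_processed()] and for
#' visualization in Topspin. Values are stored as `round(value *
#' value_scale)` with `NC_proc = 0`; the default scale preserves six
#' decimal digits of a correlation coefficient in `[-1, 1]`. The scale is
#' recorded as a `##$SCALE=` line in `procs` (a key of this dialect that
#' Topspin ignores), so [read_bruker_processed()] restores the original
#' values up to integer quantization.
#'
#' @param spectrum an [hsqc_spectrum()] or a `CorrelationPlot`.
#' @param directory_path output directory (created if needed).
#' @param value_scale positive factor mapping real values to stored
#'   integers.
#' @param sf_f2,sf_f1 spectrometer frequencies (MHz) written to the
#'   parameter files; only the ppm axes depend on them, so any positive
#'   values give a self-consistent round trip.
#' @export
write_bruker_processed <- function(spectrum, directory_path,
                                   value_scale = 1e6,
                                   sf_f2 = 600.13, sf_f1 = 150.90) {
  if (inherits(spectrum, "CorrelationPlot"))
    spectrum <- hsqc_spectrum(spectrum$grid, spectrum$coefficients,
                              sample_id = spectrum$label %||% "correlation_plot")
  stopifnot(inherits(spectrum, "HSQCSpectrum"), value_scale > 0)
  vals <- spectrum$intensities
  if (any(!is.finite(vals)))
    stop("cannot write non-finite intensities", call. = FALSE)
  ints <- round(vals * value_scale)
  imax <- .Machine$integer.max
  if (max(abs(ints)) > imax)
    stop(sprintf(
      "value_scale %g overflows 32-bit integers (max representable value is %.6g)",
      value_scale, imax / value_scale), call. = FALSE)

  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  g <- spectrum$grid
  d <- grid_spacing(g)
  # SW_p chosen so that OFFSET - i*(SW_p/SF)/SI reproduces the axis exactly
  write_procs_file(file.path(directory_path, "procs"),
                   g$n_f2, sf_f2, g$ppm_f2[1], d[["f2"]] * g$n_f2 * sf_f2, g$n_f2,
                   scale = value_scale)
  write_procs_file(file.path(directory_path, "proc2s"),
                   g$n_f1, sf_f1, g$ppm_f1[1], d[["f1"]] * g$n_f1 * sf_f1, g$n_f1)
  con <- file(file.path(directory_path, "2rr"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(ints)), con, size = 4L, endian = "little")
  invisible(directory_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
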