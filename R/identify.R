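#' Select a cross-peak from the stacked data
#'
#' Snaps a requested (1H, 13C) position to the maximum of the mean
#' spectrum over the kept grid points inside a search window — the most
#' central data point of the cross-peak, which usually coincides with the
#' local maximum. Both the requested and the resolved coordinates are
#' recorded.
#'
#' @param matrix a `SpectralMatrix` (after noise exclusion) or an
#'   `AutoscaledMatrix`; peak intensity is judged on the mean magnitude
#'   across spectra (for an `AutoscaledMatrix` the pre-scaling column
#'   means are used).
#' @param requested_ppm `c(h, c)` in ppm, inside the grid.
#' @param window half-widths `c(h, c)` in ppm around `requested_ppm`;
#'   defaults (0.03, 0.5) span a typical cross-peak footprint.
#' @return A `PeakSelection` with fields `requested_ppm`,
#'   `resolved_column` (index into the kept columns), `resolved_ppm`,
#'   `i_f1`, `i_f2`.
#' @export
select_peak <- function(matrix, requested_ppm, window = c(h = 0.03, c = 0.5)) {
  cmap <- matrix$coordinate_map
  g <- matrix$grid
  if (requested_ppm[[1]] > max(g$ppm_f2) || requested_ppm[[1]] < min(g$ppm_f2) ||
      requested_ppm[[2]] > max(g$ppm_f1) || requested_ppm[[2]] < min(g$ppm_f1))
    stop(sprintf("requested position %.3f/%.2f ppm is outside the grid",
                 requested_ppm[[1]], requested_ppm[[2]]), call. = FALSE)
  # a window narrower than one grid step could miss even an on-grid peak;
  # widen to the digital resolution when needed
  d <- grid_spacing(g)
  win_h <- max(window[[1]], d[["f2"]])
  win_c <- max(window[[2]], d[["f1"]])
  cand <- which(abs(cmap$ppm_h - requested_ppm[[1]]) <= win_h &
                abs(cmap$ppm_c - requested_ppm[[2]]) <= win_c)
  if (length(cand) == 0L)
    stop(sprintf("selected region around %.3f/%.2f ppm is all noise (no kept columns)",
                 requested_ppm[[1]], requested_ppm[[2]]), call. = FALSE)
  height <- if (inherits(matrix, "AutoscaledMatrix"))
    abs(matrix$means[cand]) else colMeans(abs(matrix$values[, cand, drop = FALSE]))
  j <- cand[which.max(height)]
  structure(
    list(requested_ppm = c(h = requested_ppm[[1]], c = requested_ppm[[2]]),
         resolved_column = j,
         resolved_ppm = c(h = cmap$ppm_h[j], c = cmap$ppm_c[j]),
         i_f1 = cmap$i_f1[j], i_f2 = cmap$i_f2[j]),
    class = "PeakSelection")
}

# 8-connected components of the nonzero points of a plot, breadth-first.
# Returns an integer label matrix aligned with `mask`.
flood_label <- function(mask) {
  lab <- array(0L, dim(mask))
  n1 <- nrow(mask); n2 <- ncol(mask)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% n1 + 1L
      c <- (p - 1L) %/% n1 + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > n1 || cc < 1L || cc > n2) next
        q <- (cc - 1L) * n1 + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Reduce a thresholded plot to a list of peaks
#'
#' A cross-peak spans several grid points, so surviving points are grouped
#' into 8-connected clusters and each cluster is reported as one peak at
#' its maximum-coefficient point. Isolated single points are valid
#' clusters.
#'
#' @param plot a `CorrelationPlot` with cutoff applied.
#' @return Data frame with one row per peak: `ppm_h`, `ppm_c`,
#'   `coefficient`, `cluster_size`.
#' @export
extract_plot_peaks <- function(plot) {
  stopifnot(inherits(plot, "CorrelationPlot"))
  if (is.null(plot$cutoff))
    stop("apply a cutoff before extracting peaks", call. = FALSE)
  mask <- plot$coefficients != 0
  if (!any(mask))
    return(data.frame(ppm_h = numeric(), ppm_c = numeric(),
                      coefficient = numeric(), cluster_size = integer()))
  lab <- flood_label(mask)
  g <- plot$grid
  out <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k)
    best <- idx[which.max(plot$coefficients[idx])]
    rc <- arrayInd(best, dim(lab))
    data.frame(ppm_h = g$ppm_f2[rc[2]], ppm_c = g$ppm_f1[rc[1]],
               coefficient = plot$coefficients[best],
               cluster_size = length(idx))
  })
  out <- do.call(rbind, out)
  out[order(-out$coefficient), , drop = FALSE]
}

#' Read a reference peak list
#'
#' Delimited text with columns `metabolite`, `delta_h_ppm`, `delta_c_ppm`
#' (extra columns are kept). Returns a data frame; use
#' [match_to_reference()] with the rows of one metabolite.
#'
#' @param path CSV/TSV file path.
#' @param sep field separator; default `","`.
#' @export
read_peak_list <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("metabolite", "delta_h_ppm", "delta_c_ppm")
  if (!all(need %in% names(tab)))
    stop(sprintf("peak list must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (any(!is.finite(tab$delta_h_ppm)) || any(!is.finite(tab$delta_c_ppm)))
    stop("peak list contains non-finite chemical shifts", call. = FALSE)
  tab
}

#' Resolution-aware matching tolerances
#'
#' A cluster apex cannot be localized better than the digital resolution
#' of the grid it was picked from: within a cluster of highly correlated
#' points the maximum-coefficient cell can sit a grid step away from the
#' true peak centre. The matching tolerance is therefore the base
#' chemical-shift tolerance widened by one grid step per dimension.
#'
#' @param grid a [spectrum_grid()].
#' @param base base tolerances `c(h, c)` in ppm (default (0.05, 0.5),
#'   typical urine shift variability).
#' @export
matching_tolerances <- function(grid, base = c(h = 0.05, c = 0.5)) {
  d <- grid_spacing(grid)
  c(h = base[[1]] + d[["f2"]], c = base[[2]] + d[["f1"]])
}

#' Score a correlation plot against a reference peak list
#'
#' Greedy nearest-first one-to-one assignment of extracted plot peaks to
#' reference peaks. The distance between a plot peak and a reference peak
#' is `max(|dH| / tol_h, |dC| / tol_c)`; pairs with distance above 1 are
#' never assigned. Matched plot peaks count as `found`, unmatched ones as
#' `extra` — extras are tracked separately and never folded into `found`,
#' since unexpected cross-peaks (e.g. long-range correlations absent from
#' the reference) are informative in their own right. Ties are broken by
#' higher coefficient, then lower 1H shift.
#'
#' @param plot_peaks data frame from [extract_plot_peaks()].
#' @param reference data frame with columns `delta_h_ppm`, `delta_c_ppm`
#'   (one metabolite's peaks), optionally `metabolite`.
#' @param tolerances `c(h, c)` matching tolerances in ppm; the defaults
#'   (0.05, 0.5) reflect typical urine chemical-shift variability.
#' @param metabolite label for the report; defaults to the reference's
#'   `metabolite` column.
#' @param selected_peak,cutoff echoed into the report.
#' @return One-row data frame of class `RecoveryReport`: `metabolite`,
#'   `selected_h_ppm`, `selected_c_ppm`, `cutoff`, `found`, `expected`,
#'   `extra`.
#' @export
match_to_reference <- function(plot_peaks, reference,
                               tolerances = c(h = 0.05, c = 0.5),
                               metabolite = NULL, selected_peak = c(NA, NA),
                               cutoff = NA_real_) {
  stopifnot(all(tolerances > 0))
  metabolite <- metabolite %||%
    (if ("metabolite" %in% names(reference) && nrow(reference))
       reference$metabolite[1] else "unknown")
  np <- nrow(plot_peaks); nr <- nrow(reference)
  found <- 0L
  if (np > 0L && nr > 0L) {
    d <- outer(seq_len(np), seq_len(nr), function(i, j)
      pmax(abs(plot_peaks$ppm_h[i] - reference$delta_h_ppm[j]) / tolerances[[1]],
           abs(plot_peaks$ppm_c[i] - reference$delta_c_ppm[j]) / tolerances[[2]]))
    pairs <- which(d <= 1, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(d[pairs],
                   -plot_peaks$coefficient[pairs[, 1]],
                   plot_peaks$ppm_h[pairs[, 1]])
      used_p <- logical(np); used_r <- logical(nr)
      for (k in ord) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (!used_p[i] && !used_r[j]) {
          used_p[i] <- TRUE; used_r[j] <- TRUE
          found <- found + 1L
        }
      }
    }
  }
  structure(
    data.frame(metabolite = metabolite,
               selected_h_ppm = selected_peak[[1]],
               selected_c_ppm = selected_peak[[2]],
               cutoff = cutoff,
               found = found, expected = nr,
               extra = np - found),
    class = c("RecoveryReport", "data.frame"))
}
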