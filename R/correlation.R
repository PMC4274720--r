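#' Autoscale the data matrix
#'
#' Mean-centres every kept column and divides by its standard deviation
#' (n - 1 denominator), so that inner products between columns become
#' Pearson correlation coefficients. Columns with zero variance cannot be
#' scaled; they are set to all-zeros and flagged rather than producing
#' NaNs.
#'
#' @param matrix a `SpectralMatrix` (typically after noise exclusion).
#' @return An object of class `AutoscaledMatrix`: the scaled values plus
#'   per-column `means`, `sds`, logical `zero_variance` flags, and the
#'   originating matrix's bookkeeping.
#' @export
autoscale <- function(matrix) {
  n <- nrow(matrix$values)
  if (n < 2L) stop("autoscaling needs n >= 2 spectra", call. = FALSE)
  mu <- colMeans(matrix$values)
  sd <- apply(matrix$values, 2L, stats::sd)
  zero <- !is.finite(sd) | sd == 0
  scaled <- sweep(matrix$values, 2L, mu, "-")
  scaled <- sweep(scaled, 2L, ifelse(zero, 1, sd), "/")
  scaled[, zero] <- 0
  structure(
    list(scaled = scaled, means = mu, sds = sd, zero_variance = zero,
         coordinate_map = matrix$coordinate_map,
         kept_mask = matrix$kept_mask, grid = matrix$grid,
         sample_ids = matrix$sample_ids,
         noise_threshold = matrix$noise_threshold),
    class = "AutoscaledMatrix")
}

# clip tiny floating-point excess beyond [-1, 1]; anything larger than the
# tolerance indicates a scaling bug and is an error, never silently clipped
clip_unit <- function(x, tol = 1e-9) {
  if (max(abs(x)) > 1 + tol)
    stop(sprintf("correlation coefficient %.6g outside [-1, 1]: scaling bug",
                 x[which.max(abs(x))]), call. = FALSE)
  pmin(pmax(x, -1), 1)
}

#' Correlation plot for one selected peak
#'
#' Computes the correlation of every kept column with the selected peak's
#' column: `c_peak = v' X / (n - 1)` on the autoscaled matrix, which is
#' exactly the Pearson correlation of the raw columns. The coefficient
#' vector is re-expanded onto the full grid, re-introducing zeros at the
#' columns omitted in the noise-exclusion step, giving a 2D field that can
#' be rendered or exported like a spectrum. Zero-variance columns get
#' coefficient 0.
#'
#' @param scaled an `AutoscaledMatrix` from [autoscale()].
#' @param selection a `PeakSelection` from [select_peak()].
#' @param label text label for the plot (e.g. metabolite name).
#' @return A `CorrelationPlot`: `coefficients` (n_f1 x n_f2 matrix),
#'   `source` selection, `cutoff` (`NULL` until [apply_cutoff()]), `grid`,
#'   `label`, and the `zero_variance`/`kept_mask` bookkeeping.
#' @export
correlate_peak <- function(scaled, selection, label = NULL) {
  stopifnot(inherits(scaled, "AutoscaledMatrix"),
            inherits(selection, "PeakSelection"))
  j <- selection$resolved_column
  if (scaled$zero_variance[j])
    stop("selected peak has no variance across spectra", call. = FALSE)
  n <- nrow(scaled$scaled)
  co <- drop(crossprod(scaled$scaled[, j], scaled$scaled)) / (n - 1)
  co[scaled$zero_variance] <- 0
  co <- clip_unit(co)

  g <- scaled$grid
  full <- numeric(g$n_f1 * g$n_f2)
  full[scaled$coordinate_map$column] <- co
  structure(
    list(coefficients = t(matrix(full, g$n_f2, g$n_f1)),
         source = selection, cutoff = NULL, grid = g,
         label = label %||% sprintf("peak %.2f/%.1f ppm",
                                    selection$resolved_ppm[[1]],
                                    selection$resolved_ppm[[2]]),
         kept_mask = scaled$kept_mask),
    class = "CorrelationPlot")
}

#' Full K x K correlation matrix (test oracle)
#'
#' `C = X' X / (n - 1)` on the autoscaled matrix — the complete correlation
#' matrix whose row j must equal [correlate_peak()] for column j. For a
#' realistic number of kept points the square matrix is enormous, which is
#' exactly why the single-peak route exists; this operation refuses to
#' allocate above `k_limit` columns and serves as the equivalence oracle
#' in tests.
#'
#' @param scaled an `AutoscaledMatrix`.
#' @param k_limit refuse above this many kept columns (default 5000).
#' @export
full_correlation_matrix <- function(scaled, k_limit = 5000L) {
  K <- ncol(scaled$scaled)
  if (K > k_limit)
    stop(sprintf(
      "%d kept columns exceed the k_limit of %d for the full correlation matrix; use correlate_peak() for single peaks",
      K, k_limit), call. = FALSE)
  n <- nrow(scaled$scaled)
  C <- crossprod(scaled$scaled) / (n - 1)
  C[scaled$zero_variance, ] <- 0
  C[, scaled$zero_variance] <- 0
  clip_unit(C)
}

#' Threshold a correlation plot
#'
#' Retains coefficients strictly greater than the cutoff and zeroes the
#' rest. Idempotent, and composing two cutoffs is equivalent to applying
#' their maximum. The cutoff is recorded on the plot.
#'
#' @param plot a `CorrelationPlot`.
#' @param cutoff value in `[-1, 1]`.
#' @export
apply_cutoff <- function(plot, cutoff) {
  stopifnot(inherits(plot, "CorrelationPlot"),
            cutoff >= -1, cutoff <= 1)
  plot$coefficients[plot$coefficients <= cutoff] <- 0
  plot$cutoff <- max(cutoff, plot$cutoff %||% -1)
  plot
}

#' Single-point unit plot for a one-peak metabolite
#'
#' Metabolites with only one HSQC cross-peak produce no correlation
#' partners; for the merged constructed spectrum they are injected as a
#' unit-value singleton plot at their cross-peak position.
#'
#' @param grid a [spectrum_grid()].
#' @param ppm `c(h, c)` position in ppm.
#' @param label metabolite name.
#' @export
singleton_plot <- function(grid, ppm, label) {
  i2 <- nearest_index(grid$ppm_f2, ppm[[1]])
  i1 <- nearest_index(grid$ppm_f1, ppm[[2]])
  if (is.na(i1) || is.na(i2))
    stop(sprintf("singleton position %.3f/%.2f ppm outside grid", ppm[[1]], ppm[[2]]),
         call. = FALSE)
  co <- base::matrix(0, grid$n_f1, grid$n_f2)
  co[i1, i2] <- 1
  sel <- structure(list(requested_ppm = ppm,
                        resolved_ppm = c(grid$ppm_f2[i2], grid$ppm_f1[i1]),
                        resolved_column = NA_integer_, i_f1 = i1, i_f2 = i2),
                   class = "PeakSelection")
  structure(list(coefficients = co, source = sel, cutoff = 1 - 1e-12,
                 grid = grid, label = label, kept_mask = NULL),
            class = "CorrelationPlot")
}

#' Merge correlation plots into a constructed spectrum
#'
#' Combines thresholded plots by pointwise maximum of the surviving
#' coefficients — each point of the constructed spectrum shows its best
#' correlation to any selected peak, and every plot's support is
#' preserved. A provenance table records, for every surviving point, which
#' plot(s) contributed a nonzero value there.
#'
#' @param plots non-empty list of `CorrelationPlot`s on one grid, cutoffs
#'   applied.
#' @return A list with `spectrum` (an [hsqc_spectrum()] of the merged
#'   coefficients) and `provenance` (data frame: `i_f1`, `i_f2`, `ppm_h`,
#'   `ppm_c`, `value`, `plots`).
#' @export
merge_plots <- function(plots) {
  if (length(plots) == 0L) stop("no plots to merge", call. = FALSE)
  stopifnot(all(vapply(plots, inherits, TRUE, "CorrelationPlot")))
  g <- plots[[1]]$grid
  for (p in plots[-1])
    if (!grids_equal(p$grid, g))
      stop(sprintf("plot '%s' is on a different grid", p$label), call. = FALSE)
  if (any(vapply(plots, function(p) is.null(p$cutoff), TRUE)))
    stop("all plots must have a cutoff applied before merging", call. = FALSE)

  merged <- base::matrix(0, g$n_f1, g$n_f2)
  contrib <- vector("list", length(plots))
  for (k in seq_along(plots)) {
    merged <- pmax(merged, plots[[k]]$coefficients)
    contrib[[k]] <- which(plots[[k]]$coefficients != 0)
  }
  idx <- sort(unique(unlist(contrib)))
  labels <- vapply(plots, function(p) p$label %||% "plot", "")
  prov_plots <- vapply(idx, function(i)
    paste(labels[vapply(contrib, function(ci) i %in% ci, TRUE)], collapse = ";"),
    "")
  rc <- arrayInd(idx, dim(merged))
  provenance <- data.frame(
    i_f1 = rc[, 1], i_f2 = rc[, 2],
    ppm_h = g$ppm_f2[rc[, 2]], ppm_c = g$ppm_f1[rc[, 1]],
    value = merged[idx], plots = prov_plots)
  list(spectrum = hsqc_spectrum(g, merged, sample_id = "merged_correlation_plots"),
       provenance = provenance)
}

#' @export
print.CorrelationPlot <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("CorrelationPlot '%s': source %.3f/%.2f ppm, cutoff %s, %d nonzero points\n",
              x$label, x$source$resolved_ppm[[1]], x$source$resolved_ppm[[2]],
              if (is.null(x$cutoff)) "none" else sprintf("%.3g", x$cutoff), nz))
  invisible(x)
}
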