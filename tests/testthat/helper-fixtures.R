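# Shared fixtures: tiny grids and spectra with planted peaks, plus the
# independent brute-force oracles the module tests compare against.

small_grid <- function(n_f2 = 12L, n_f1 = 8L, offset_f2 = 10, sw_f2 = 6,
                       offset_f1 = 150, sw_f1 = 80) {
  grid_from_params(n_f2, n_f1, offset_f2, sw_f2, offset_f1, sw_f1)
}

noise_spectrum <- function(grid, sd = 1, id = "noise", seed = 1) {
  set.seed(seed)
  hsqc_spectrum(grid, matrix(rnorm(grid$n_f1 * grid$n_f2, 0, sd),
                             grid$n_f1, grid$n_f2), sample_id = id)
}

# spectrum that is zero except for one rectangular peak of given height at
# grid indices (i1, i2)
peak_spectrum <- function(grid, i1, i2, height = 10, id = "peak") {
  m <- matrix(0, grid$n_f1, grid$n_f2)
  m[i1, i2] <- height
  hsqc_spectrum(grid, m, sample_id = id)
}

# SpectralMatrix built directly from a values matrix on a matching grid
matrix_from_values <- function(values) {
  n <- nrow(values); K <- ncol(values)
  grid <- small_grid(n_f2 = K, n_f1 = 2L)
  spectra <- lapply(seq_len(n), function(i) {
    m <- matrix(0, 2L, K)
    m[1, ] <- values[i, ]
    hsqc_spectrum(grid, m, sample_id = paste0("s", i))
  })
  stack_spectra(spectra)
}

nearest_index_for_test <- function(axis, ppm) which.min(abs(axis - ppm))

# PeakSelection pointing at an exact kept column (bypasses the window-based
# maximum snap, which is free to prefer a taller neighbor)
select_col <- function(sm, j) {
  cm <- sm$coordinate_map
  structure(list(
    requested_ppm = c(h = cm$ppm_h[j], c = cm$ppm_c[j]),
    resolved_column = j,
    resolved_ppm = c(h = cm$ppm_h[j], c = cm$ppm_c[j]),
    i_f1 = cm$i_f1[j], i_f2 = cm$i_f2[j]),
    class = "PeakSelection")
}

# brute-force keep rule: column kept iff any |value| >= threshold
brute_keep <- function(values, threshold) {
  apply(values, 2L, function(col) any(abs(col) >= threshold))
}

# independent connected-component count: repeated neighbor expansion from
# each unvisited cell, 8-connectivity
brute_cluster_count <- function(mask) {
  visited <- mask & FALSE
  n1 <- nrow(mask); n2 <- ncol(mask)
  count <- 0L
  for (r0 in seq_len(n1)) for (c0 in seq_len(n2)) {
    if (!mask[r0, c0] || visited[r0, c0]) next
    count <- count + 1L
    frontier <- matrix(c(r0, c0), 1L)
    while (nrow(frontier)) {
      nxt <- NULL
      for (k in seq_len(nrow(frontier))) {
        r <- frontier[k, 1]; c <- frontier[k, 2]
        if (visited[r, c]) next
        visited[r, c] <- TRUE
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= n1 && cc >= 1 && cc <= n2 &&
              mask[rr, cc] && !visited[rr, cc])
            nxt <- rbind(nxt, c(rr, cc))
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(), 0, 2) else nxt
    }
  }
  count
}

# mixture model restricted to named metabolites from the packaged library
library_model <- function(names, n = 50L, seed = 1L, ...) {
  lib <- default_metabolite_library()
  mixture_model(lib[names], n = n, seed = seed, ...)
}

# coefficient at the grid point nearest a ppm position (max over the
# immediate neighborhood, since jitter can move the apex by one cell)
coef_near <- function(plot, ppm_h, ppm_c) {
  g <- plot$grid
  i2 <- which.min(abs(g$ppm_f2 - ppm_h))
  i1 <- which.min(abs(g$ppm_f1 - ppm_c))
  max(plot$coefficients[max(1, i1 - 1):min(g$n_f1, i1 + 1),
                        max(1, i2 - 1):min(g$n_f2, i2 + 1)])
}

# full small pipeline: spectra -> masked matrix
masked_matrix <- function(spectra, threshold = NULL, multiplier = 5) {
  sm <- stack_spectra(spectra)
  thr <- if (is.null(threshold)) suggest_noise_threshold(sm, multiplier) else threshold
  apply_noise_exclusion(sm, thr)
}
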