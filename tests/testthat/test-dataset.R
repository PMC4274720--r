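# Calibration, normalization, stacking and noise exclusion

test_that("calibration leaves an already-referenced spectrum unchanged", {
  grid <- small_grid(n_f2 = 20L, n_f1 = 10L, offset_f2 = 2, sw_f2 = 4,
                     offset_f1 = 20, sw_f1 = 40)
  i2 <- nearest_index_for_test(grid$ppm_f2, 0)
  i1 <- nearest_index_for_test(grid$ppm_f1, 0)
  s <- peak_spectrum(grid, i1, i2, height = 100)
  ref <- c(grid$ppm_f2[i2], grid$ppm_f1[i1]) # reference exactly on-grid
  cal <- calibrate_to_reference(s, search_window = list(f2 = c(-1, 1),
                                                        f1 = c(-10, 10)),
                                reference_ppm = ref)
  expect_equal(cal$grid$ppm_f2, grid$ppm_f2)
  expect_equal(cal$grid$ppm_f1, grid$ppm_f1)
})

test_that("a peak planted k grid points off shifts the axes by exactly k steps", {
  grid <- small_grid(n_f2 = 30L, n_f1 = 16L, offset_f2 = 2, sw_f2 = 4,
                     offset_f1 = 20, sw_f1 = 40)
  d <- grid_spacing(grid)
  i2 <- nearest_index_for_test(grid$ppm_f2, 0)
  i1 <- nearest_index_for_test(grid$ppm_f1, 0)
  s <- peak_spectrum(grid, i1 + 2L, i2 - 3L, height = 100) # 3 left in 1H, 2 in 13C
  cal <- calibrate_to_reference(s, search_window = list(f2 = c(-1, 1),
                                                        f1 = c(-15, 15)),
                                reference_ppm = c(grid$ppm_f2[i2],
                                                  grid$ppm_f1[i1]))
  # the planted maximum sits 3 steps left (downfield) of the reference in
  # 1H, so the whole 1H axis must come down by 3 steps for it to read the
  # reference value; conversely the 13C axis moves up by 2 steps
  expect_equal(cal$grid$ppm_f2, grid$ppm_f2 - 3 * d[["f2"]], tolerance = 1e-12)
  expect_equal(cal$grid$ppm_f1, grid$ppm_f1 + 2 * d[["f1"]], tolerance = 1e-12)
  expect_identical(cal$intensities, s$intensities)
})

test_that("calibration flags spectra whose window is all noise, errors off-grid", {
  grid <- small_grid(n_f2 = 30L, n_f1 = 16L, offset_f2 = 2, sw_f2 = 4,
                     offset_f1 = 20, sw_f1 = 40)
  s <- noise_spectrum(grid, sd = 1, seed = 3)
  expect_warning(cal <- calibrate_to_reference(
    s, search_window = list(f2 = c(-1, 0.5), f1 = c(-15, 10))),
    "uncalibrated")
  expect_true(isTRUE(attr(cal, "uncalibrated")))
  expect_error(calibrate_to_reference(
    s, search_window = list(f2 = c(50, 60), f1 = c(-15, 10))), "outside")
})

test_that("total-intensity normalization is scale-invariant and idempotent", {
  grid <- small_grid()
  s <- noise_spectrum(grid, sd = 2, seed = 8)
  s5 <- hsqc_spectrum(grid, s$intensities * 5, "x5")
  expect_equal(normalize_total_intensity(s)$intensities,
               normalize_total_intensity(s5)$intensities, tolerance = 1e-12)
  n1 <- normalize_total_intensity(s)
  expect_equal(normalize_total_intensity(n1)$intensities, n1$intensities,
               tolerance = 1e-12)
  flat <- hsqc_spectrum(grid, matrix(7, grid$n_f1, grid$n_f2))
  G <- grid$n_f1 * grid$n_f2
  expect_equal(unique(as.vector(normalize_total_intensity(flat)$intensities)),
               1e6 / G)
  neg <- hsqc_spectrum(grid, matrix(-1, grid$n_f1, grid$n_f2))
  expect_error(normalize_total_intensity(neg), "positive")
})

test_that("stacking flattens f1-major with a complete coordinate map", {
  grid <- small_grid(n_f2 = 3L, n_f1 = 4L)
  a <- noise_spectrum(grid, seed = 1, id = "a")
  b <- noise_spectrum(grid, seed = 2, id = "b")
  sm <- stack_spectra(list(a, b))
  expect_equal(dim(sm$values), c(2L, 12L))
  expect_equal(nrow(sm$coordinate_map), 12L)
  # row-major (f1-major) order: first n_f2 columns are the first 13C row
  expect_equal(sm$values[1, 1:3], a$intensities[1, ])
  expect_equal(sm$values[1, 4:6], a$intensities[2, ])
  # un-flattening reproduces the spectrum exactly
  expect_identical(unstack_row(sm, 2)$intensities, b$intensities)
})

test_that("stacking refuses mismatched grids and fewer than two spectra", {
  a <- noise_spectrum(small_grid(), id = "a")
  b <- noise_spectrum(small_grid(offset_f2 = 10.5), id = "b")
  expect_error(stack_spectra(list(a)), "at least 2")
  expect_error(stack_spectra(list(a, b)), "grid mismatch for sample 'b'")
})

test_that("suggested threshold matches the MAD noise scale of pure noise", {
  grid <- small_grid(n_f2 = 100L, n_f1 = 50L)
  spectra <- lapply(1:4, function(i) noise_spectrum(grid, sd = 1, seed = i,
                                                    id = paste0("n", i)))
  sm <- stack_spectra(spectra)
  # unit-variance Gaussian noise: MAD ~ 1, so 5 x MAD ~ 5
  expect_equal(suggest_noise_threshold(sm, 5), 5, tolerance = 0.05)
  expect_equal(suggest_noise_threshold(sm, 0), 0)
  spike <- matrix(0, 3, 50); spike[2, 10] <- 100
  expect_warning(thr <- suggest_noise_threshold(matrix_from_values(spike)),
                 "manually")
  expect_equal(thr, 0)
})

test_that("noise exclusion keeps a column iff any spectrum clears the threshold", {
  sm <- matrix_from_values(rbind(c(1, 0.1, 0.2, 5),
                                 c(0.3, 0.2, 0.1, 4)))
  # threshold 0: vacuous, nothing removed
  expect_equal(ncol(apply_noise_exclusion(sm, 0)$values), ncol(sm$values))
  ex <- apply_noise_exclusion(sm, 0.5)
  kept_cols <- ex$coordinate_map$column
  expect_equal(ex$values, rbind(c(1, 5), c(0.3, 4)), ignore_attr = TRUE)
  expect_equal(sum(ex$kept_mask), 2L)
  expect_error(apply_noise_exclusion(sm, 100), "no signal columns")
})

test_that("exclusion matches the brute-force keep rule and is monotone", {
  set.seed(42)
  for (k in 1:20) {
    vals <- matrix(rnorm(5 * 12), 5, 12)
    sm <- matrix_from_values(vals)
    thr1 <- runif(1, 0, 1.5); thr2 <- thr1 + runif(1, 0, 1)
    keep1 <- brute_keep(vals, thr1)
    ex1 <- apply_noise_exclusion(sm, thr1)
    expect_equal(ncol(ex1$values), sum(keep1))
    expect_equal(unname(ex1$values), unname(vals[, keep1, drop = FALSE]))
    # monotone: raising the threshold never re-admits a column, and
    # re-exclusion composes with fresh exclusion at the higher threshold
    ex12 <- apply_noise_exclusion(ex1, thr2)
    ex2 <- apply_noise_exclusion(sm, thr2)
    expect_true(all(ex12$coordinate_map$column %in% ex1$coordinate_map$column))
    expect_identical(ex12$kept_mask, ex2$kept_mask)
  }
})
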