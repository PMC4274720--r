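# Processed-Bruker and portable-container I/O

test_that("write then read round-trips axes and intensities", {
  grid <- small_grid()
  s <- noise_spectrum(grid, sd = 3, seed = 4)
  d <- file.path(tempdir(), "rt_bruker")
  write_bruker_processed(s, d, value_scale = 1e6)
  r <- read_bruker_processed(d)
  expect_equal(r$grid$ppm_f2, grid$ppm_f2, tolerance = 1e-9)
  expect_equal(r$grid$ppm_f1, grid$ppm_f1, tolerance = 1e-9)
  # quantization error at most half an integer step
  expect_lt(max(abs(r$intensities - s$intensities)), 0.5 / 1e6 + 1e-12)
})

test_that("a 1024 x 512 directory reads back as a 1024 x 512 grid", {
  grid <- default_grid()
  m <- matrix(0, grid$n_f1, grid$n_f2)
  m[100, 200] <- 1
  d <- file.path(tempdir(), "full_size")
  write_bruker_processed(hsqc_spectrum(grid, m), d, value_scale = 1e4)
  r <- read_bruker_processed(d)
  expect_equal(r$grid$n_f2, 1024L)
  expect_equal(r$grid$n_f1, 512L)
  expect_equal(which(r$intensities != 0), (200 - 1) * 512 + 100)
})

test_that("stored integers obey round(value * scale) with NC_proc = 0", {
  grid <- small_grid(n_f2 = 2L, n_f1 = 2L)
  s <- hsqc_spectrum(grid, matrix(c(0.5, 1.0, -0.5, 0.0), 2, 2))
  d <- file.path(tempdir(), "quant")
  write_bruker_processed(s, d, value_scale = 100)
  ints <- readBin(file.path(d, "2rr"), "integer", n = 4, size = 4,
                  endian = "little")
  expect_setequal(ints, c(50L, -50L, 100L, 0L))
})

test_that("tiled 2rr de-tiling matches a hand-unrolled index map", {
  # 8 (F2) x 4 (F1) points, XDIM2 = 4, XDIM1 = 2, integers 0..31 in file
  # order: brute-force the expected matrix by walking tiles explicitly
  d <- file.path(tempdir(), "tiled")
  dir.create(d, showWarnings = FALSE)
  writeBin(as.integer(0:31), file.path(d, "2rr"), size = 4, endian = "little")
  writeLines(c("##$SI= 8", "##$SF= 600", "##$OFFSET= 10", "##$SW_p= 4800",
               "##$XDIM= 4", "##$BYTORDP= 0", "##$NC_proc= 0"),
             file.path(d, "procs"))
  writeLines(c("##$SI= 4", "##$SF= 150", "##$OFFSET= 100", "##$SW_p= 3000",
               "##$XDIM= 2", "##$BYTORDP= 0", "##$NC_proc= 0"),
             file.path(d, "proc2s"))
  expected <- matrix(NA_real_, 4, 8)
  p <- 0
  for (tr in 0:1) for (tc in 0:1)       # tile grid: 2 x 2 tiles
    for (wr in 0:1) for (wc in 0:3) {   # within tile: 2 rows x 4 cols
      expected[tr * 2 + wr + 1, tc * 4 + wc + 1] <- p
      p <- p + 1
    }
  r <- read_bruker_processed(d)
  expect_identical(r$intensities, expected)
  # de-tiling is a bijection: all 32 values appear exactly once
  expect_setequal(as.vector(r$intensities), 0:31)
})

test_that("big-endian 2rr and NC_proc scaling are honoured", {
  d <- file.path(tempdir(), "bigend")
  dir.create(d, showWarnings = FALSE)
  writeBin(as.integer(c(1, 2, 3, 4, 5, 6)), file.path(d, "2rr"),
           size = 4, endian = "big")
  writeLines(c("##$SI= 3", "##$SF= 600", "##$OFFSET= 10", "##$SW_p= 1800",
               "##$XDIM= 3", "##$BYTORDP= 1", "##$NC_proc= 2"),
             file.path(d, "procs"))
  writeLines(c("##$SI= 2", "##$SF= 150", "##$OFFSET= 100", "##$SW_p= 3000",
               "##$XDIM= 2", "##$BYTORDP= 1", "##$NC_proc= 2"),
             file.path(d, "proc2s"))
  r <- read_bruker_processed(d)
  expect_equal(r$intensities, matrix(c(1, 2, 3, 4, 5, 6) * 4, 2, 3,
                                     byrow = TRUE))
  expect_equal(r$scale_exponent, 2L)
})

test_that("missing files, missing parameters and bad sizes raise named errors", {
  d <- file.path(tempdir(), "broken")
  unlink(d, recursive = TRUE); dir.create(d)
  expect_error(read_bruker_processed(d), class = "hsqccor_missing_file")
  writeBin(as.integer(1:6), file.path(d, "2rr"), size = 4, endian = "little")
  expect_error(read_bruker_processed(d), class = "hsqccor_missing_file")
  writeLines(c("##$SI= 3", "##$SF= 600", "##$OFFSET= 10", "##$SW_p= 1800",
               "##$XDIM= 3", "##$BYTORDP= 0", "##$NC_proc= 0"),
             file.path(d, "procs"))
  writeLines(c("##$SI= 2", "##$SF= 150", "##$OFFSET= 100", "##$SW_p= 3000",
               "##$BYTORDP= 0"), file.path(d, "proc2s"))
  expect_error(read_bruker_processed(d), class = "hsqccor_missing_parameter")
  writeLines(c("##$SI= 5", "##$SF= 150", "##$OFFSET= 100", "##$SW_p= 3000",
               "##$XDIM= 5", "##$BYTORDP= 0", "##$NC_proc= 0"),
             file.path(d, "proc2s"))
  expect_error(read_bruker_processed(d), class = "hsqccor_corrupt_data")
})

test_that("writer refuses non-finite values and integer overflow", {
  grid <- small_grid(n_f2 = 2L, n_f1 = 2L)
  s <- hsqc_spectrum(grid, matrix(c(1, 2, 3, 4), 2, 2))
  expect_error(write_bruker_processed(s, tempfile(), value_scale = 1e9),
               "max representable")
  bad <- s; bad$intensities[1] <- Inf
  expect_error(write_bruker_processed(bad, tempfile()), "non-finite")
})

test_that("portable container round-trips bitwise and preserves order", {
  grid <- small_grid()
  spectra <- lapply(1:3, function(i) noise_spectrum(grid, id = paste0("u", i),
                                                    seed = i))
  f <- tempfile(fileext = ".h5")
  write_portable(spectra, f)
  back <- read_portable(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$intensities, spectra[[i]]$intensities)
    expect_identical(back[[i]]$sample_id, spectra[[i]]$sample_id)
  }
})

test_that("portable container rejects empty and mixed-grid input", {
  expect_error(write_portable(list(), tempfile()), "empty")
  a <- noise_spectrum(small_grid(), id = "ok")
  b <- noise_spectrum(small_grid(offset_f2 = 11), id = "offender")
  err <- tryCatch(write_portable(list(a, b), tempfile()),
                  error = function(e) conditionMessage(e))
  expect_match(err, "offender")
})

test_that("random grids round-trip through both formats (property)", {
  set.seed(99)
  for (k in 1:5) {
    grid <- small_grid(n_f2 = sample(4:20, 1), n_f1 = sample(3:10, 1),
                       offset_f2 = runif(1, 5, 15), sw_f2 = runif(1, 2, 10),
                       offset_f1 = runif(1, 100, 180), sw_f1 = runif(1, 30, 90))
    s <- noise_spectrum(grid, sd = 5, seed = k)
    f <- tempfile(fileext = ".h5")
    write_portable(list(s, s), f)
    expect_identical(read_portable(f)[[1]]$intensities, s$intensities)
    d <- file.path(tempdir(), paste0("prop", k))
    write_bruker_processed(s, d, value_scale = 1e5)
    r <- read_bruker_processed(d)
    expect_equal(r$grid$ppm_f2, grid$ppm_f2, tolerance = 1e-9)
    expect_lt(max(abs(r$intensities - s$intensities)), 0.5 / 1e5 + 1e-12)
  }
})
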