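#' Serialize a noise-masked data matrix
#'
#' Stores a `SpectralMatrix` in a single HDF5 file (values, keep-mask,
#' axes, sample ids, threshold) so that pipeline stages can be run as
#' separate processes and composed.
#'
#' @param matrix a `SpectralMatrix`.
#' @param path output file.
#' @export
write_matrix_h5 <- function(matrix, path) {
  stopifnot(inherits(matrix, "SpectralMatrix"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(matrix$values, path, "values")
  rhdf5::h5write(as.integer(matrix$kept_mask), path, "kept_mask")
  rhdf5::h5write(matrix$grid$ppm_f1, path, "ppm_f1")
  rhdf5::h5write(matrix$grid$ppm_f2, path, "ppm_f2")
  rhdf5::h5write(matrix$sample_ids, path, "sample_ids")
  rhdf5::h5write(matrix$noise_threshold, path, "noise_threshold")
  invisible(path)
}

#' @rdname write_matrix_h5
#' @export
read_matrix_h5 <- function(path) {
  if (!file.exists(path))
    stop_class("hsqccor_missing_file", "missing matrix file: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  grid <- spectrum_grid(ppm_f2 = as.numeric(rhdf5::h5read(path, "ppm_f2")),
                        ppm_f1 = as.numeric(rhdf5::h5read(path, "ppm_f1")))
  mask <- as.logical(rhdf5::h5read(path, "kept_mask"))
  i_f1 <- rep(seq_len(grid$n_f1), each = grid$n_f2)
  i_f2 <- rep(seq_len(grid$n_f2), times = grid$n_f1)
  cmap <- data.frame(column = seq_along(mask), i_f1 = i_f1, i_f2 = i_f2,
                     ppm_c = grid$ppm_f1[i_f1], ppm_h = grid$ppm_f2[i_f2])
  structure(
    list(values = as.matrix(rhdf5::h5read(path, "values")),
         coordinate_map = cmap[mask, , drop = FALSE],
         kept_mask = mask, grid = grid,
         sample_ids = as.character(rhdf5::h5read(path, "sample_ids")),
         noise_threshold = as.numeric(rhdf5::h5read(path, "noise_threshold"))),
    class = "SpectralMatrix")
}

#' Assemble and validate a pipeline configuration
#'
#' All pipeline behaviour is driven by one configuration object (readable
#' from YAML/JSON via [read_run_config()]). Validation happens before any
#' I/O.
#'
#' @param input path to a portable container ([write_portable()]), or
#'   `NULL` when `simulate` is given.
#' @param simulate `NULL`, or a list with any of `n`, `n_f2`, `n_f1`,
#'   `noise_sigma`, `shift_jitter_factor`, `include_singletons` — the
#'   dataset is then generated from the packaged library.
#' @param calibrate logical; re-reference every spectrum to TSP (0, 0).
#' @param normalize logical; total-intensity normalization (default off).
#' @param noise_multiplier advisory threshold = multiplier x MAD (used
#'   when `noise_threshold` is `NULL`).
#' @param noise_threshold explicit intensity threshold, or `NULL`.
#' @param peaks data frame `metabolite`, `delta_h_ppm`, `delta_c_ppm` of
#'   peaks to correlate from; default: the packaged library's selected
#'   peaks.
#' @param cutoff correlation cutoff in `[-1, 1]` applied to every plot.
#' @param reference reference peak table for scoring (`NULL` to skip);
#'   defaults to the packaged library when simulating.
#' @param tolerances matching tolerances `c(h, c)` in ppm, or `NULL` to
#'   derive them from the grid via [matching_tolerances()].
#' @param out_dir output directory.
#' @param seed integer seed for simulation.
#' @export
run_config <- function(input = NULL, simulate = list(), calibrate = TRUE,
                       normalize = FALSE, noise_multiplier = 5,
                       noise_threshold = NULL, peaks = NULL, cutoff = 0.9,
                       reference = NULL, tolerances = NULL,
                       out_dir = "hsqccor_run", seed = 1L) {
  if (!is.numeric(cutoff) || cutoff < -1 || cutoff > 1)
    stop(sprintf("cutoff %.4g outside [-1, 1]", cutoff), call. = FALSE)
  if (!is.null(input) && !file.exists(input))
    stop(sprintf("input container does not exist: %s", input), call. = FALSE)
  if (is.null(input) && is.null(simulate))
    stop("either an input container or a simulate block is required",
         call. = FALSE)
  structure(
    list(input = input, simulate = simulate, calibrate = calibrate,
         normalize = normalize, noise_multiplier = noise_multiplier,
         noise_threshold = noise_threshold, peaks = peaks, cutoff = cutoff,
         reference = reference, tolerances = tolerances, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "RunConfig")
}

#' @rdname run_config
#' @param path YAML (or JSON) configuration file whose keys mirror the
#'   `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$tolerances)) cfg$tolerances <- unlist(cfg$tolerances)
  if (!is.null(cfg$peaks)) cfg$peaks <- as.data.frame(cfg$peaks)
  do.call(run_config, cfg)
}

pipeline_log <- function(lines, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  c(lines, msg)
}

#' Run the full correlation-plot pipeline
#'
#' import (or simulate) -> calibrate -> (normalize) -> stack ->
#' noise-mask -> per-peak correlate -> cutoff -> export -> score.
#' Outputs, under `config$out_dir`: one processed-Bruker directory and
#' one peak CSV per correlation plot, the merged constructed spectrum
#' (Bruker + provenance CSV), a recovery report CSV when a reference is
#' available, the stacked dataset as a portable container, and a JSON
#' run manifest (config echo, package version, seed, per-step log).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the recovery report, plot peak tables,
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()

  # --- import or simulate -------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    spectra <- read_portable(config$input)
    log <- pipeline_log(log, "import: %d spectra from %s",
                        length(spectra), config$input)
  } else {
    sim <- config$simulate
    lib <- default_metabolite_library(
      include_singletons = isTRUE(sim$include_singletons))
    model <- mixture_model(lib, n = sim$n %||% 50L,
                           noise_sigma = sim$noise_sigma %||% 0.01,
                           seed = config$seed)
    if (!is.null(sim$shift_jitter_factor))
      model <- stress_jitter(model, sim$shift_jitter_factor)
    grid <- default_grid(n_f2 = sim$n_f2 %||% 1024L, n_f1 = sim$n_f1 %||% 512L)
    ds <- generate_dataset(model, grid)
    spectra <- ds$spectra
    truth <- ds$truth
    utils::write.csv(ds$truth, file.path(config$out_dir, "ground_truth_peaks.csv"),
                     row.names = FALSE)
    log <- pipeline_log(log, "simulate: %d spectra, %d metabolites, %d x %d grid",
                        length(spectra), length(lib), grid$n_f2, grid$n_f1)
  }

  # --- calibrate / normalize ---------------------------------------------
  if (isTRUE(config$calibrate)) {
    spectra <- lapply(spectra, calibrate_to_reference)
    log <- pipeline_log(log, "calibrate: TSP-referenced %d spectra", length(spectra))
  }
  if (isTRUE(config$normalize)) {
    spectra <- lapply(spectra, normalize_total_intensity)
    log <- pipeline_log(log, "normalize: total-intensity, %d spectra", length(spectra))
  }

  # --- stack + noise mask -------------------------------------------------
  sm <- stack_spectra(spectra)
  thr <- config$noise_threshold %||%
    suggest_noise_threshold(sm, config$noise_multiplier)
  sm <- apply_noise_exclusion(sm, thr)
  log <- pipeline_log(log, "mask-noise: threshold %.5g, kept %d of %d columns",
                      thr, ncol(sm$values), length(sm$kept_mask))
  write_portable(spectra, file.path(config$out_dir, "dataset.h5"))
  scaled <- autoscale(sm)

  # --- peaks to correlate -------------------------------------------------
  peaks <- config$peaks
  if (is.null(peaks)) {
    lib <- default_metabolite_library()
    peaks <- do.call(rbind, lapply(lib, function(m) {
      sel <- m$peaks[m$peaks$selected == 1, ][1, ]
      data.frame(metabolite = m$name, delta_h_ppm = sel$delta_h_ppm,
                 delta_c_ppm = sel$delta_c_ppm)
    }))
  }
  reference <- config$reference %||% truth
  tol <- config$tolerances %||% matching_tolerances(sm$grid)

  plots <- list(); reports <- list(); peak_tables <- list()
  for (k in seq_len(nrow(peaks))) {
    met <- peaks$metabolite[k]
    sel <- select_peak(sm, c(peaks$delta_h_ppm[k], peaks$delta_c_ppm[k]))
    plot <- apply_cutoff(correlate_peak(scaled, sel, label = met), config$cutoff)
    pk <- extract_plot_peaks(plot)
    safe <- gsub("[^A-Za-z0-9._-]", "_", met)
    write_bruker_processed(plot, file.path(config$out_dir, paste0("plot_", safe)))
    utils::write.csv(pk, file.path(config$out_dir, paste0("peaks_", safe, ".csv")),
                     row.names = FALSE)
    if (!is.null(reference)) {
      ref <- reference[reference$metabolite == met, , drop = FALSE]
      reports[[met]] <- match_to_reference(
        pk, ref, tolerances = tol, metabolite = met,
        selected_peak = c(peaks$delta_h_ppm[k], peaks$delta_c_ppm[k]),
        cutoff = config$cutoff)
    }
    plots[[met]] <- plot
    peak_tables[[met]] <- pk
  }
  log <- pipeline_log(log, "correlate: %d plots at cutoff %.3g",
                      length(plots), config$cutoff)

  # --- merge + score ------------------------------------------------------
  merged <- merge_plots(plots)
  write_bruker_processed(merged$spectrum, file.path(config$out_dir, "merged_plot"))
  utils::write.csv(merged$provenance,
                   file.path(config$out_dir, "merged_provenance.csv"),
                   row.names = FALSE)
  recovery <- NULL
  if (length(reports)) {
    recovery <- do.call(rbind, reports)
    utils::write.csv(recovery, file.path(config$out_dir, "recovery_report.csv"),
                     row.names = FALSE)
    log <- pipeline_log(log, "score: %d/%d metabolites fully recovered",
                        sum(recovery$found == recovery$expected & recovery$extra == 0),
                        nrow(recovery))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hsqccor")),
    seed = config$seed,
    config = config[setdiff(names(config), c("peaks", "reference"))],
    log = log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(recovery = recovery, plots = plots, peak_tables = peak_tables,
                 matrix = sm, out_dir = config$out_dir))
}
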