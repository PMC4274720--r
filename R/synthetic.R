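#' @title Synthetic multi-sample HSQC mixtures with known ground truth
#' @description
#' The study design this package targets — dozens of metabolites whose
#' concentrations vary independently across ~50 urine samples — is
#' emulated here so the whole pipeline can be validated against known
#' ground truth. Cross-peaks are rendered as 2D Gaussians (correlation
#' depends only on amplitude co-variation, so the simplest shape
#' suffices), concentrations are log-normal (strictly positive, heavy
#' tailed, as urinary metabolites are), small per-peak chemical-shift
#' jitter emulates pH/ionic-strength variation, and a constant-amplitude
#' TSP reference peak at (0, 0) ppm is always included so calibration is
#' exercised.
#' @name synthetic_data
NULL

#' Construct a synthetic metabolite
#'
#' @param name metabolite name.
#' @param peaks data frame with columns `delta_h_ppm`, `delta_c_ppm`,
#'   `amplitude` (relative, in (0, 1]), `lw_h_ppm`, `lw_c_ppm` (Gaussian
#'   sd line widths, ppm), `long_range` (0/1 flag for weak 2J/3J
#'   cross-peaks).
#' @export
synthetic_metabolite <- function(name, peaks) {
  need <- c("delta_h_ppm", "delta_c_ppm", "amplitude", "lw_h_ppm",
            "lw_c_ppm", "long_range")
  stopifnot(all(need %in% names(peaks)), nrow(peaks) >= 1L)
  if (any(peaks$amplitude <= 0 | peaks$amplitude > 1))
    stop("relative amplitudes must lie in (0, 1]", call. = FALSE)
  if (any(peaks$lw_h_ppm <= 0 | peaks$lw_c_ppm <= 0))
    stop("line widths must be positive", call. = FALSE)
  structure(list(name = name, peaks = peaks), class = "SyntheticMetabolite")
}

load_library_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  # locale-independent grouping/order so datasets are reproducible across
  # systems (collation of names like "trans-..." varies with LC_COLLATE)
  lapply(split(tab, factor(tab$metabolite, levels = unique(tab$metabolite))),
         function(p) synthetic_metabolite(p$metabolite[1], p))
}

#' Packaged synthetic urine metabolite library
#'
#' 23 multi-peak metabolites (2 to 9 cross-peaks each, including a weak
#' long-range cross-peak on phenylacetylglutamine), optionally extended
#' with 7 single-cross-peak metabolites. Selected-peak positions follow
#' typical urinary metabolite shifts; companion cross-peak coordinates
#' are synthetic, chosen to be resolvable on a 512 x 256 grid.
#'
#' @param include_singletons also include the 7 one-peak metabolites.
#' @return List of [synthetic_metabolite()] objects (ordered by name).
#' @export
default_metabolite_library <- function(include_singletons = FALSE) {
  lib <- load_library_csv(system.file("extdata",
    "metabolite_library_synthetic.csv", package = "hsqccor", mustWork = TRUE))
  if (include_singletons)
    lib <- c(lib, load_library_csv(system.file("extdata",
      "singleton_metabolites_synthetic.csv", package = "hsqccor",
      mustWork = TRUE)))
  lib[order(names(lib), method = "radix")]
}

#' Mixture model: metabolites, concentrations, noise, jitter
#'
#' @param metabolites list of [synthetic_metabolite()]s.
#' @param n number of samples (spectra); default 50.
#' @param log_conc_sd sd of log-concentrations; default 0.5.
#' @param concentration_correlation M x M correlation matrix of
#'   log-concentrations (symmetric PSD, unit diagonal), emulating
#'   pathway-driven co-variation. Default: identity, except a 0.7
#'   correlation between citric and isocitric acid when both are present
#'   (one deliberately co-regulated pair).
#' @param noise_sigma sd of additive white noise; default 0.01 intensity
#'   units (peak amplitudes are of order `concentration x amplitude`,
#'   i.e. ~1).
#' @param shift_jitter_sd per-peak, per-sample chemical-shift jitter sd
#'   `c(h, c)` in ppm; default (0.005, 0.05), well under one grid step.
#' @param tsp_amplitude constant amplitude of the TSP reference peak.
#' @param seed integer seed; all randomness in the model flows from it.
#' @export
mixture_model <- function(metabolites, n = 50L, log_conc_sd = 0.5,
                          concentration_correlation = NULL,
                          noise_sigma = 0.01,
                          shift_jitter_sd = c(h = 0.005, c = 0.05),
                          tsp_amplitude = 5, seed = 1L) {
  stopifnot(length(metabolites) >= 1L, n >= 2L,
            all(vapply(metabolites, inherits, TRUE, "SyntheticMetabolite")))
  M <- length(metabolites)
  nm <- vapply(metabolites, `[[`, "", "name")
  if (is.null(concentration_correlation)) {
    concentration_correlation <- diag(M)
    pair <- match(c("Citric acid", "Isocitric acid"), nm)
    if (!anyNA(pair))
      concentration_correlation[pair[1], pair[2]] <-
        concentration_correlation[pair[2], pair[1]] <- 0.7
  }
  cc <- concentration_correlation
  if (!isSymmetric(unname(cc)) || any(abs(diag(cc) - 1) > 1e-12))
    stop("concentration_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  if (min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("concentration_correlation is not positive semi-definite",
         call. = FALSE)
  structure(
    list(metabolites = metabolites, names = nm, n = as.integer(n),
         log_conc_sd = log_conc_sd, concentration_correlation = cc,
         noise_sigma = noise_sigma,
         shift_jitter_sd = shift_jitter_sd,
         tsp_amplitude = tsp_amplitude, seed = as.integer(seed)),
    class = "MixtureModel")
}

#' Draw the sample-by-metabolite concentration matrix
#'
#' Log-concentrations are multivariate normal with sd `log_conc_sd` and
#' the model's correlation structure; concentrations are their exponent,
#' hence strictly positive with median 1. Deterministic for a fixed model
#' seed.
#'
#' @param model a [mixture_model()].
#' @export
sample_concentrations <- function(model) {
  set.seed(model$seed)
  M <- length(model$metabolites)
  Sigma <- model$log_conc_sd^2 * model$concentration_correlation
  logc <- MASS::mvrnorm(model$n, mu = rep(0, M), Sigma = Sigma)
  logc <- base::matrix(logc, model$n, M, dimnames = list(NULL, model$names))
  exp(logc)
}

# add one 2D Gaussian to a spectrum matrix, in place-ish; evaluated only on
# a +/- 4 sd footprint for speed
add_gaussian <- function(mat, grid, ch, cc, amp, lwh, lwc) {
  d <- grid_spacing(grid)
  i2 <- nearest_index(grid$ppm_f2, ch)
  i1 <- nearest_index(grid$ppm_f1, cc)
  if (is.na(i1) || is.na(i2)) {
    warning(sprintf("peak at %.3f/%.2f ppm falls outside the grid; dropped",
                    ch, cc), call. = FALSE)
    return(mat)
  }
  w2 <- ceiling(4 * lwh / d[["f2"]]); w1 <- ceiling(4 * lwc / d[["f1"]])
  r2 <- max(1L, i2 - w2):min(grid$n_f2, i2 + w2)
  r1 <- max(1L, i1 - w1):min(grid$n_f1, i1 + w1)
  gh <- exp(-(grid$ppm_f2[r2] - ch)^2 / (2 * lwh^2))
  gc <- exp(-(grid$ppm_f1[r1] - cc)^2 / (2 * lwc^2))
  mat[r1, r2] <- mat[r1, r2] + amp * outer(gc, gh)
  mat
}

#' Render one sample's spectrum
#'
#' Sum over metabolites of concentration times each cross-peak's 2D
#' Gaussian (amplitude = concentration x relative amplitude; centres
#' jittered per peak and sample), plus the constant, unjittered TSP
#' reference peak at (0, 0) ppm and white noise. The per-sample random stream is seeded as
#' `model$seed + sample_index`, so any sample renders identically whether
#' drawn alone or through [generate_dataset()].
#'
#' @param model a [mixture_model()].
#' @param sample_index which sample to render.
#' @param grid target [spectrum_grid()]; default [default_grid()].
#' @param concentrations optional pre-drawn matrix from
#'   [sample_concentrations()] (drawn if missing).
#' @export
render_spectrum <- function(model, sample_index, grid = default_grid(),
                            concentrations = NULL) {
  stopifnot(sample_index >= 1L, sample_index <= model$n)
  if (is.null(concentrations)) concentrations <- sample_concentrations(model)
  set.seed(model$seed + as.integer(sample_index))
  mat <- base::matrix(0, grid$n_f1, grid$n_f2)
  jh <- model$shift_jitter_sd[[1]]; jc <- model$shift_jitter_sd[[2]]
  for (m in seq_along(model$metabolites)) {
    met <- model$metabolites[[m]]
    conc <- concentrations[sample_index, m]
    for (p in seq_len(nrow(met$peaks))) {
      pk <- met$peaks[p, ]
      mat <- add_gaussian(mat, grid,
                          pk$delta_h_ppm + stats::rnorm(1, 0, jh),
                          pk$delta_c_ppm + stats::rnorm(1, 0, jc),
                          conc * pk$amplitude, pk$lw_h_ppm, pk$lw_c_ppm)
    }
  }
  # TSP is rendered without jitter: the reference compound is chosen for a
  # pH- and matrix-insensitive shift, which is what makes it a reference
  mat <- add_gaussian(mat, grid, 0, 0, model$tsp_amplitude, 0.018, 0.35)
  if (model$noise_sigma > 0)
    mat <- mat + stats::rnorm(length(mat), 0, model$noise_sigma)
  hsqc_spectrum(grid, mat, sample_id = sprintf("synthetic_%03d", sample_index))
}

#' Generate a full synthetic dataset with ground truth
#'
#' @param model a [mixture_model()].
#' @param grid target grid; default [default_grid()].
#' @return List with `spectra` (list of [hsqc_spectrum()]),
#'   `concentrations` (n x M), and `truth` — the planted peak table
#'   (`metabolite`, `delta_h_ppm`, `delta_c_ppm`, `amplitude`,
#'   `long_range`, `selected`), the scoring ground truth.
#' @export
generate_dataset <- function(model, grid = default_grid()) {
  conc <- sample_concentrations(model)
  spectra <- lapply(seq_len(model$n), function(i)
    render_spectrum(model, i, grid, concentrations = conc))
  truth <- do.call(rbind, lapply(model$metabolites, function(m) {
    p <- m$peaks
    p$metabolite <- m$name
    p[, c("metabolite", "delta_h_ppm", "delta_c_ppm", "amplitude",
          "long_range", intersect("selected", names(p)))]
  }))
  rownames(truth) <- NULL
  list(spectra = spectra, concentrations = conc, truth = truth, model = model)
}

#' Stress preset: triple the chemical-shift jitter
#'
#' Returns a copy of the model with 3x the shift jitter — the regime where
#' shift variation starts to erode intra-metabolite correlation, the
#' documented failure mode of alignment-free correlation.
#'
#' @param model a [mixture_model()].
#' @param factor jitter multiplier; default 3.
#' @export
stress_jitter <- function(model, factor = 3) {
  model$shift_jitter_sd <- model$shift_jitter_sd * factor
  model
}
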