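# hsqccor

Metabolite identification from statistically correlated 2D ¹H-¹³C HSQC NMR
spectra.

## The problem

A 2D ¹H-¹³C HSQC spectrum of a biofluid such as urine contains hundreds of
cross-peaks from dozens of metabolites, and assigning which cross-peaks
belong to which compound is the bottleneck of NMR metabolomics. When the
*same* experiment is recorded on many samples, statistical total
correlation spectroscopy (STOCSY) offers a way out: cross-peaks of one
compound rise and fall together with its concentration across samples, so
their intensities are almost perfectly correlated, while peaks of other
compounds are not. `hsqccor` applies this idea to series of 2D HSQC
spectra: it builds per-metabolite *correlation plots* — coefficient fields
that look like HSQC spectra of pure compounds — and scores them against
reference peak lists.

For a series of *n* spectra flattened into an autoscaled (per-column
mean 0, sd 1) data matrix **X** (*n* × *K*), the full correlation matrix is

> **C** = **X**ᵗ**X** / (n − 1)

but **C** is enormous for realistic *K*, so the package computes only the
correlations to one chosen cross-peak column **v**:

> **c** = **v**ᵗ**X** / (n − 1)

which is exactly the Pearson correlation of every grid point with the
selected peak. Re-introducing zeros at noise-masked points and reshaping
**c** onto the original grid gives the 2D correlation plot; thresholding
at a high cutoff (e.g. > 0.9) leaves the cross-peaks of one compound. The
approach needs no magnetization transfer, so it also connects isolated
spin systems and weak long-range (HMBC-like) cross-peaks to their parent
compound.

The package covers the full workflow:

- **I/O** — processed Bruker 2D data (`2rr` + `procs`/`proc2s`, tiled or
  untiled, either byte order), an HDF5 portable container for whole
  spectrum series, and export of correlation plots back to the Bruker
  dialect for viewing in Topspin.
- **Preprocessing** — TSP chemical-shift calibration (whole grid points,
  no interpolation), optional total-intensity normalization, spectral
  vectorization, and the all-spectra noise mask (a grid point is kept if
  *any* sample shows signal there).
- **Correlation** — autoscaling, single-peak correlation plots, the full
  correlation-matrix oracle, strict cutoffs, merging of plots into a
  constructed spectrum with provenance.
- **Identification** — window-based peak selection, 8-connected cluster
  reduction of thresholded plots, and greedy one-to-one matching against
  reference peak lists with found/expected/extra bookkeeping.
- **Synthetic data** — a mixture simulator (Gaussian cross-peaks,
  log-normal concentrations, optional pathway correlation, per-peak
  chemical-shift jitter, additive noise, a TSP reference peak) with a
  packaged 23-metabolite synthetic urine library used to validate every
  claim above against known ground truth.

## Worked example

Simulate a 50-sample urine-like study on a 512 × 256 grid, mask the noise,
and build the correlation plot of phenylacetylglutamine from its aromatic
peak at 7.41/131.5 ppm:

```r
library(hsqccor)

lib   <- default_metabolite_library()            # 23 synthetic metabolites
model <- mixture_model(lib, n = 50, seed = 1)
ds    <- generate_dataset(model, default_grid(512, 256))

sm  <- stack_spectra(lapply(ds$spectra, calibrate_to_reference))
thr <- suggest_noise_threshold(sm)               # 5 x MAD = 0.05078
sm  <- apply_noise_exclusion(sm, thr)
sm
#> SpectralMatrix: 50 spectra x 1665 kept columns (of 131072; threshold 0.05078)

sel  <- select_peak(sm, c(7.41, 131.5))
plot <- apply_cutoff(correlate_peak(autoscale(sm), sel,
                                    label = "Phenylacetylglutamine"), 0.8)
extract_plot_peaks(plot)
#>   ppm_h  ppm_c coefficient cluster_size
#> 1 7.419 131.72      1.0000           12
#> 6 2.262  37.62      0.9883           11
#> 2 7.356 123.98      0.9872           13
#> 5 2.450  33.75      0.9870           13
#> 9 1.887  28.59      0.9859           12
#> 8 2.012  31.82      0.9858            9
#> 4 3.669  45.35      0.9812           12
#> 3 4.200  56.95      0.9788           10
#> 7 2.262  30.53      0.9710            6
```

The noise mask reduced 131 072 grid points to 1 665 informative columns.
The nine reported peaks are the metabolite's two aromatic and six
aliphatic cross-peaks — two isolated spin systems connected purely by
concentration statistics — plus the weak long-range cross-peak planted at
2.27/30.4 ppm, which correlates at 0.97 despite its low intensity. Scoring
against the ground-truth peak list confirms complete recovery:

```r
truth <- subset(ds$truth, metabolite == "Phenylacetylglutamine")
match_to_reference(extract_plot_peaks(plot),
                   data.frame(metabolite = truth$metabolite,
                              delta_h_ppm = truth$delta_h_ppm,
                              delta_c_ppm = truth$delta_c_ppm),
                   tolerances = matching_tolerances(sm$grid))
#>              metabolite ... found expected extra
#> 1 Phenylacetylglutamine ...     9        9     0
```

`run_pipeline(run_config(...))` chains all of the above for every
metabolite and writes correlation plots (Bruker format + CSV), a merged
constructed spectrum, a recovery report and a run manifest. The same
pipeline is scriptable from a shell via `exec/hsqccor`
(`simulate`, `import`, `calibrate`, `normalize`, `mask-noise`,
`correlate`, `merge`, `score`, `run`).

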