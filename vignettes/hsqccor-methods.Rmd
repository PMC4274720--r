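---
title: "Correlation plots from series of 2D HSQC spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation plots from series of 2D HSQC spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistical model

Across a series of samples of the same biofluid, the intensity of every
cross-peak of a metabolite is proportional to that metabolite's
concentration in each sample. If spectra from *n* samples are flattened
into a matrix **X** (*n* rows, one column per retained grid point) and
each column is autoscaled — mean-centred and divided by its standard
deviation (computed with the *n* − 1 denominator) — then the inner
product of two columns divided by *n* − 1 is exactly their Pearson
correlation. Columns fed by the same metabolite correlate near +1;
columns fed by different, independently varying metabolites correlate
near 0; columns fed by metabolites under shared regulation (same pathway)
correlate at the concentration correlation, which is below the
within-compound value. This ordering is what makes a high correlation
cutoff act as a compound-purity filter.

`hsqccor` computes, for one selected cross-peak column **v**,
**c** = **v**ᵗ**X**/(n − 1) rather than the full **C** =
**X**ᵗ**X**/(n − 1): for a 1024 × 512 grid the full matrix would have
~2.7 × 10¹¹ entries, while one row costs a single matrix-vector product.
`full_correlation_matrix()` exists as the equivalence oracle for tests
and refuses to allocate above a configurable column limit (default 5000).
The tests verify that the single-peak route, the full-matrix row and an
independent textbook Pearson computation agree to 10⁻¹⁰.

Assumptions worth stating explicitly:

- *Common grid.* All spectra must share one acquisition and processing
  scheme. `stack_spectra()` demands exact axis equality and never
  resamples; a mismatch is an error naming the first differing axis
  value, because silent interpolation would both hide acquisition errors
  and alter the intensities the correlation is computed from.
- *No peak alignment.* Sample-to-sample chemical-shift variation is
  tolerated only as far as a peak stays essentially on its grid cell;
  this is the method's documented operating envelope (see the jitter
  study below).
- *Concentration-driven intensities.* Any per-sample global intensity
  factor (dilution, receiver gain) is irrelevant to Pearson correlation;
  the optional total-intensity normalization exists for interpretability
  of plotted rows, is off by default, and is scale-invariant and
  idempotent.

## Pipeline steps and their parameters

**Calibration** (`calibrate_to_reference`). Each spectrum is re-referenced
to the TSP peak: the maximum inside a search window (default ±0.3 ppm ¹H,
±5 ppm ¹³C around 0/0 ppm) is located and both axes are shifted by whole
grid steps so that this maximum lands on the reference position.
Intensities are never interpolated — sub-pixel shifts would modify the
values entering the correlation. The ¹³C reference value of TSP is taken
as 0 ppm (configurable; conventions differ). If the window maximum does
not exceed a robust noise floor (5 × MAD of the whole spectrum) the
spectrum is returned unshifted, flagged `uncalibrated`, with a warning.

**Vectorization and noise mask** (`stack_spectra`,
`apply_noise_exclusion`). Spectra are flattened F1-major (all ¹H points
of the first ¹³C row first); the coordinate map records every column's
grid indices and shifts so plots are orientation-stable and the
flatten/reshape round trip is the identity. A column is removed only when
*all* n samples are below the threshold, so a metabolite present in a
single sample survives. Magnitudes are compared (|value| ≥ threshold) by
default because processed spectra carry negative noise excursions and
occasional phase artifacts; a signed comparison is available. The
exclusion is monotone in the threshold and composes. The suggested
threshold is `multiplier × MAD` of all matrix values (default multiplier
5): in sparse spectra the majority of points are baseline noise, making
the MAD a robust noise-scale estimate. It is advisory only — the
operation takes an explicit threshold, mirroring practice, where the
threshold is chosen by inspecting a plotted row vector.

**Peak selection** (`select_peak`). The user requests a (δ¹H, δ¹³C)
position; the selection snaps to the maximum of the mean spectrum over
kept columns within a window (default half-widths 0.03 ppm ¹H, 0.5 ppm
¹³C — about one cross-peak footprint). The window is never narrower than
one grid step per dimension, since a smaller window could miss even a
perfectly placed peak on a coarse grid. Both requested and resolved
coordinates are recorded.

**Correlation, cutoff, merging.** Coefficients at zero-variance columns
are set to 0 and flagged (not NaN), keeping plots renderable and
exportable. Values may exceed ±1 only by floating-point error; anything
beyond 1 + 10⁻⁹ raises an error (it would indicate a scaling bug), the
rest is clipped. The cutoff retains coefficients *strictly greater* than
the threshold; applying two cutoffs equals applying their maximum.
Negative correlations are computed and retained in the plot object, but a
positive cutoff naturally hides them, matching how plots are read in
practice. Merging uses the pointwise maximum of the surviving
coefficients, with a provenance table naming every contributing plot per
point: the maximum preserves each plot's support and keeps the merged
value interpretable as "best correlation to any selected peak". How the
merge is performed is genuinely open (sum and overlay are defensible);
maximum was chosen for those two properties. Metabolites with a single
cross-peak produce no correlation partners and enter the merged spectrum
as unit-value singleton points.

**Cluster reduction and matching** (`extract_plot_peaks`,
`match_to_reference`). A cross-peak spans several grid points that all
correlate with the driver, so surviving points are grouped into
8-connected clusters and each cluster is reported at its
maximum-coefficient point. Matching against a reference list is greedy,
nearest-first and one-to-one, with distance
max(|Δδ¹H|/tol_H, |Δδ¹³C|/tol_C); ties break by higher coefficient, then
lower δ¹H. Reference lists are tiny (≤ 9 peaks), so optimal assignment
would buy nothing over greedy. Unmatched surviving peaks are counted as
`extra`, never folded into `found` — unexpected correlating peaks (e.g.
long-range cross-peaks absent from a database entry) are informative and
should be surfaced, not hidden. Base tolerances (0.05 ppm ¹H, 0.5 ppm
¹³C) reflect typical urine shift variability; `matching_tolerances()`
widens them by one grid step per dimension because a cluster apex cannot
be localized better than the digital resolution — within a cluster the
coefficients are nearly tied, and the reported apex can legitimately sit
one cell from the true centre (on a 256-point ¹³C axis one cell is
0.645 ppm, already larger than the base tolerance).

## The synthetic study

The packaged generator stands in for a 50-patient urine study whose
spectra are not publicly available; its defaults are the study
conditions, chosen once:

- **Grid**: 1024 × 512 points covering 16 ppm ¹H / 165 ppm ¹³C with left
  edges 12.7 / 157.5 ppm (the processed-data convention for a spectrum
  acquired with carrier offsets 4.7 / 75 ppm). Validation studies use
  512 × 256 over the same window to keep runtimes in seconds; all
  documented behaviour holds on the coarser grid.
- **Library**: 23 multi-peak metabolites (85 cross-peaks, 2–9 each)
  named and positioned after common urinary metabolites, plus 7
  single-cross-peak metabolites. The selected-peak coordinates follow
  typical literature shifts; companion cross-peak coordinates are
  synthetic, placed so that every pair of peaks is resolvable on the
  coarsest supported grid: within a metabolite |Δδ¹H| ≥ 0.20 ppm or
  |Δδ¹³C| ≥ 3.5 ppm (closer same-compound peaks would bridge into one
  cluster through tail points that share the concentration driver and
  therefore survive any cutoff), between metabolites ≥ 0.10 / 2.0 ppm
  (mixed cells decorrelate below a high cutoff on their own). One
  metabolite, phenylacetylglutamine, carries a low-amplitude
  (relative 0.1) long-range cross-peak flagged as such — the HMBC-like
  feature whose recovery the tests check.
- **Peak shape**: 2D Gaussians with sd linewidths 0.03 ppm ¹H / 0.5 ppm
  ¹³C (≈ one grid cell; realistic for processed 600 MHz HSQC data).
  Correlation depends only on amplitude co-variation, so shape realism
  beyond adequate digital resolution buys nothing. Under-resolved peaks
  (linewidth well below one cell) make peak-top intensity hypersensitive
  to shift jitter and are the main way to break the method — which is a
  property of the data, not of the algorithm.
- **Concentrations**: log-normal, sd 0.5 on the log scale (median 1, a
  realistic heavy-tailed dispersion for urinary metabolites; the value
  is the package's own choice). Pathway co-regulation is
  emulated by a correlation matrix on log-concentrations; the default
  links citric and isocitric acid at 0.7.
- **Jitter**: every cross-peak centre is shifted independently per
  sample by Gaussian jitter, sd 0.005 ppm ¹H / 0.05 ppm ¹³C —
  well under one grid step, the regime in which no alignment is needed.
  Jitter is applied per peak rather than once per spectrum because pH
  and ionic strength shift different resonances differently; the
  per-peak version is also the stricter test of the no-alignment claim.
  A `stress_jitter()` preset triples it, which measurably lowers
  intra-metabolite correlations (the acceptance script reports both
  values). The TSP reference peak is rendered without jitter: reference
  compounds are chosen precisely for matrix-insensitive shifts, and a
  jittered reference would randomize the whole-grid-point calibration
  shift across samples.
- **Noise**: additive white Gaussian noise, sd 0.01 intensity units
  against peak amplitudes of order 1 — strong-signal SNR typical of
  cryoprobe HSQC on abundant urinary metabolites. The 5 × MAD threshold
  then sits near 0.05 and keeps ~1–2 % of grid points.

What the generator deliberately does not emulate: J-coupling fine
structure, Lorentzian/Voigt lineshapes, t₁ noise ridges, water/urea
suppression artifacts, phase distortion, baseline roll, and peak overlap
within a grid cell. Consequently, passing tests demonstrate the
statistical machinery — vectorization, masking, correlation, clustering,
scoring — under realistic variation of concentration, shift and noise;
they do not certify behaviour in heavily overlapped spectral regions,
where the correlation at a shared grid cell is a mixture and drops below
any high cutoff (the method's known failure mode on real data, alongside
extreme shift variation).

## Numerical choices and degenerate inputs

- Autoscaling uses the n − 1 denominator throughout, so inner products
  are exactly Pearson coefficients; zero-variance columns are zeroed and
  flagged rather than producing NaN.
- Correlating *from* a zero-variance column is an error (there is no
  direction of variation to correlate with).
- Axis uniformity is enforced to a relative 10⁻⁶; round trips through
  the Bruker dialect preserve axes to 10⁻⁹ ppm and intensities to one
  integer quantization step (the writer stores round(value × scale) with
  the scale recorded in `procs`, default 10⁶, preserving six decimal
  digits of a correlation coefficient).
- The Bruker reader accepts tiled (submatrix) and untiled `2rr` files in
  either byte order; the writer always emits untiled little-endian data,
  the simplest layout Topspin accepts. De-tiling is exhaustively tested
  as a bijection on small tile layouts.
- An empty spectrum list, mixed grids in a container, a threshold that
  removes every column, a cutoff outside [−1, 1], and a selection window
  containing no kept columns are all named errors, raised before any
  output is written.
- All generator randomness flows from one integer seed; per-sample
  streams are derived as seed + sample index, so a single spectrum
  renders identically whether drawn alone or within a dataset, across
  platforms (metabolite ordering is locale-independent by construction).

## Problem sizes

The test suite validates algebraic identities on small random matrices
(n ∈ {3, 5, 10}, K ≤ 200, plus exhaustive 2 × 3 matrices for the noise
rule), and the full pipeline on 50-spectrum datasets at 512 × 256 —
a deliberate choice that keeps the whole suite under a minute while
exercising every code path at study-realistic n. The acceptance script
uses the same sizes.

## Known limitations

- Overlapping signals on one grid cell dilute correlation; the package
  reports the resulting missed peaks honestly (`found < expected`)
  rather than attempting deconvolution.
- Severe chemical-shift variation requires alignment, which is out of
  scope here; the stress preset quantifies the degradation instead.
- Matching is per-metabolite against its own reference list; it does not
  attempt global assignment across a panel of candidate metabolites.
- The multi-point-per-peak variant (selecting all points of a cross-peak
  and merging the resulting plots) is not implemented.
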