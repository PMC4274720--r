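Package: hsqccor
Title: Metabolite Identification from Statistically Correlated 2D HSQC NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical correlation of a series of 2D 1H-13C HSQC NMR spectra
    (STOCSY applied to heteronuclear 2D data) to produce per-metabolite
    correlation plots resembling spectra of pure compounds, for unambiguous
    metabolite identification in complex mixtures such as urine. Includes a
    reader and writer for processed Bruker data (2rr plus procs/proc2s), an
    HDF5-based portable container, chemical-shift calibration against a TSP
    reference, noise-masked spectral vectorization, single-peak Pearson
    correlation plots with cutoff thresholding and plot merging, matching of
    correlation plots against reference peak lists, and a synthetic
    multi-sample HSQC mixture simulator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
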