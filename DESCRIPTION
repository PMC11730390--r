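Package: neonirs
Title: Neonatal fNIRS Speech-Discrimination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of block-design functional
    near-infrared spectroscopy (fNIRS) recordings of neonatal speech
    discrimination. Provides a seeded synthetic-cohort generator
    (two-wavelength optical intensities, stimulus schedules, language
    outcomes), the full preprocessing chain from raw intensities to
    per-condition hemodynamic response averages (optical density,
    signal-to-noise pruning, motion-artifact detection, spline and
    wavelet motion correction, zero-phase band-pass filtering, modified
    Beer-Lambert conversion with age- and wavelength-dependent
    differential pathlength factors, block averaging with baseline
    correction and inclusion bookkeeping), per-subject speech
    discrimination metrics (SP, SP_L, SP_R), the hemispheric laterality
    index, and cohort statistics (mixed 2x2x2 repeated-measures ANOVA
    with partial eta squared, Lilliefors normality screening,
    Mann-Whitney U, Spearman and Pearson correlation tables with
    Bonferroni families, slope-homogeneity tests, a socioeconomic-status
    composite, and z-score classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    yaml,
    stats,
    utils
Suggests:
    rhdf5,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
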