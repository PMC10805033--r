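Package: filaclock
Title: Single-Cell Circadian Trace Analysis for Heterocyst-Forming
    Cyanobacterial Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-cell fluorescence time-lapse traces from
    filamentous cyanobacteria (e.g. Anabaena) growing under nitrogen
    deprivation, where filaments differentiate nitrogen-fixing heterocysts
    that partition the filament into vegetative cell intervals.  Provides a
    long-format trace data model with lineage and interval resolution; the
    synchronization index R (ratio of the temporal variance of the
    population-mean signal to the mean per-cell temporal variance) with
    expression-noise (squared coefficient of variation) and neighbour /
    cross-interval Pearson correlation structure; circadian minima, period
    and amplitude estimation by parabolic and piecewise parabola-line fits;
    autofluorescence-decay onset detection by a constant-then-parabola
    stitching-point fit; mapping of differentiation onsets to circadian
    phase with bootstrap histograms and circular summaries; and a synthetic
    filament-cohort generator with ground truth for parameter-recovery
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
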