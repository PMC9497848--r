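Package: movesync
Title: Movement Synchrony Measures for Dyadic Motion-Energy Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a battery of interpersonal movement-synchrony measures
    from bivariate motion-energy time series: global cross-correlation
    variants, windowed cross-correlation and cross-lagged correlation with a
    person-shuffling pseudo-synchrony test, surrogate synchrony (SUSY) and
    surrogate concordance (SUCO) with segment-shuffled surrogates, windowed
    cross-lagged correlation/regression with peak picking into
    synchronization intervals, kernel-based mutual information with jackknife
    bias correction, and windowed cross-recurrence quantification analysis.
    Includes motion-energy extraction from grayscale frame stacks, a
    synthetic-data generator producing coupled dyads with ground-truth
    synchronization intervals and cohorts with group and symptom structure,
    and convergent and predictive validity statistics (correlation matrices,
    parallel analysis, maximum-likelihood factor analysis with oblimin
    rotation, Kruskal-Wallis tests with Hedges g, symptom correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    KernSmooth,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr
Config/testthat/edition: 3
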