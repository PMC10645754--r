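Package: dendrocycles
Title: Periodicity Analysis of Dendrometer Stem-Radius Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to decompose high-frequency (hourly) point-dendrometer
    records of tree stem radius into irreversible growth (GRO) and reversible
    tree water deficit (TWD) under the zero-growth assumption, and to test
    which periodic drivers the resulting series oscillate with. Includes a
    continuous wavelet transform (Morlet, Paul, derivative-of-Gaussian
    mothers) with Monte-Carlo significance, a low-precision analytic lunar
    ephemeris for synodic phase and new-moon epochs, generalized additive
    attribution of per-period mean wavelet power to temperature, vapour
    pressure deficit and lunar phase, lunar-phase-bin summary statistics with
    autocorrelation-corrected confidence intervals, and a synthetic-data
    generator that emulates the statistical structure of dendrometer and
    meteorological series with an injectable lunar-period component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
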