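Package: rhythmfit
Title: Non-Sinusoidal Waveform Models for Rhythm Detection in Omics Time
    Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects rhythmic features in temporal omics data (bulk and
    single-cell transcriptomics, proteomics, metabolomics) by fitting four
    bounded waveform families per molecule: an extended harmonic oscillator
    with an exponential amplitude-change envelope, a two-component
    pseudo-square wave, a two-component cycloid wave, and a periodic gated
    Gaussian transient. The best model is selected by sum of squared
    residuals, rhythmicity is called with a zero-amplitude lack-of-fit
    F-test confirmed by Kendall's tau agreement between observed and fitted
    values, p-values are Benjamini-Hochberg adjusted across features, and
    regulatory behaviour (damped, forced, stable) is classified from the
    amplitude-change coefficient. Includes a seeded synthetic-panel
    generator, tidy accessors, and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
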