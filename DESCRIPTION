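Package: trailcycle
Title: Sampling-Based Modeling of Cell-Cycle Progression and TRAIL-Induced Apoptosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the bidirectional interplay between cell-cycle
    progression and TRAIL-induced extrinsic apoptosis from single-cell
    time-lapse tracks. Provides a virtual-cell-population simulator with
    lognormal phase durations and a normalized cell-cycle coordinate,
    right-censored distribution fitting with BIC model selection,
    quantification of the survivorship bias that cell death imposes on
    phase-length measurements, sampling-based likelihood estimation of the
    TRAIL-induced phase prolongation z, inference of initial cell-cycle
    positions from track data, and grid/KDE-likelihood fitting of a
    piecewise-linear point-of-apoptosis-deceleration (PAD) model of death
    timing, with chi-square confidence regions and synchronization sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    KernSmooth,
    fitdistrplus,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
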