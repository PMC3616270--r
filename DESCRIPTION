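Package: crawlwave
Title: Central Pattern Generator Model of Peristaltic Waves in Crawling Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a central pattern generator (CPG) for peristaltic
    crawling in Drosophila larvae: a chain of eight Wilson-Cowan
    excitatory/inhibitory population units with nearest-neighbour coupling,
    an optional stretch-sensitive sensory feedback extension, and a
    two-sided (left/right hemisegment) variant with four kinds of
    contralateral coupling. Provides a compiled fixed-step and adaptive
    Runge-Kutta integrator, wave quantification metrics (contraction
    intervals at a threshold, normalized contraction durations,
    intersegmental phase lags, wave counting, validity classification,
    left/right synchrony), scripted parameter-sweep experiments (drive
    strength/duration grids, intersegmental coupling grids, connection-noise
    robustness, sensory feedback sweeps, two-sided synchrony phase
    diagrams), and the published behavioural summary statistics as
    reference fixtures for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
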