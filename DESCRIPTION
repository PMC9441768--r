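Package: pspeckle
Title: Triblock-Copolymer Micelle Model of Paraspeckle Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models spherical paraspeckles as core-shell micelles of ABC
    triblock copolymers (NEAT1_2 ribonucleoprotein complexes) whose assembly
    is driven by transcription. Implements the micelle free energy (core
    stretching, A-B interactions, surface tension, Daoud-Cotton shell
    brushes, and mixing entropy of the terminal A blocks), the master
    equation for transcript association and dissociation at the
    transcription site, its analytic steady-state size distribution, and
    the effective free energy whose minimisation gives the most probable
    aggregation number. Provides parameter sweeps, discontinuity detection,
    bisection for the critical A-block length, phase-diagram construction,
    ggplot2 visualisations, and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
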