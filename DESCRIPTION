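Package: dnakink
Title: Free-Energy Landscapes and Kink Analysis for Rigid-Base DNA Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to probe the kinkability of double-stranded DNA at the
    base-pair-step level. Implements rigid-base energy models in the roll,
    tilt and excess-twist coordinates (harmonic, anharmonic with cubic and
    quartic couplings, and one-dimensional phenomenological bending models),
    an umbrella-sampling protocol with harmonic roll/twist restraints, a
    Metropolis Monte Carlo sampler that emulates biased trajectories, a
    two-dimensional weighted histogram analysis method (WHAM) to reconstruct
    unbiased free-energy landscapes, stepwise polynomial surface fitting,
    flattening/inflection detection on one-dimensional profiles, and
    classification of twist-bend versus pure-bend kinks from step-parameter
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
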