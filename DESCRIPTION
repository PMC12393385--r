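Package: permeatr
Title: Ion Permeation Analysis for Membrane-Channel Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of ion permeation through pentameric ligand-gated ion
    channels from molecular-dynamics-style trajectories. Detects complete
    transmembrane crossing events inside a bounded cylindrical counting
    region, converts event tallies into single-channel currents and
    conductances, fits single-Poisson and double-Poisson (hypoexponential)
    waiting-time models and log-normal event-duration models, classifies
    axial versus lateral-fenestration entry pathways, and computes channel
    profile observables (pore radius, ion density, hydration number,
    residue position density) together with an axial diffusion estimate.
    Includes a stochastic trajectory generator with ground-truth event
    labels so that every stage of the pipeline can be validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
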