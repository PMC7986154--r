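Package: irtchem
Title: Independent Reaction Time and Step-by-Step Simulation of Water
    Radiolysis Chemistry and DNA Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of diffusion-controlled reactions among
    water-radiolysis species (hydrated electron, hydroxyl radical, hydrogen
    atom, hydronium, hydroxide, molecular hydrogen, hydrogen peroxide) and
    between those species and a static chromatin-fiber DNA model. Implements
    a synchronous, position-explicit independent reaction time (IRT) stepper
    and a reference step-by-step (SBS) Brownian-dynamics stepper with dynamic
    time steps, minimum-time-step schedules and Brownian-bridge compensation.
    Includes closed-form first-passage reaction-time samplers for totally and
    partially diffusion-controlled reactions (with Debye effective-distance
    corrections for charged pairs and spin statistical factors), synthetic
    electron-spur and proton-track sources, a 40 nm heterochromatin-fiber
    reactive-sink geometry, radiochemical G-value scoring with a water
    material-balance audit, and direct/indirect primary DNA damage scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
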