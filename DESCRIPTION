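Package: methanesig
Title: Planetary Context Assessment for Atmospheric Methane Biosignatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and a decision framework for assessing atmospheric
    methane as a biosignature on habitable-zone terrestrial exoplanets.
    Includes a batch-melting model of oxygen-fugacity-dependent graphite
    sequestration in reduced magmas with Monte Carlo uncertainty propagation,
    diffusion-limited hydrogen-escape lifetimes of methane on melted Titan-like
    volatile-rich planets, a column/lifetime flux-balance estimator linking
    observed CH4 mixing ratios to required surface replenishment fluxes, a
    machine-readable compendium of known abiotic CH4 source fluxes, a
    tri-state rule engine classifying planet scenarios as candidate
    biosignatures versus likely false positives, and seeded generators for
    synthetic planet-scenario ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
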