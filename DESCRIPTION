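Package: amypom
Title: Kinetic and Binding Analysis of Polyoxometalate Inhibition of
    Amyloid Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for characterising small-cluster
    inhibitors (polyoxometalates) of S100A9 amyloid formation: isodesmic
    polymerization fits of thioflavin-T kinetic traces, exponential modelling
    of the apparent rate versus inhibitor concentration, one-site
    binding-isotherm fits of fluorescence titrations, sphere-of-action
    analysis of acrylamide quenching, weighted spectral differences for
    circular dichroism spectra, and median/median-deviation summaries of AFM
    fibril cross-sectional heights. Includes seeded synthetic-data generators
    for every input so all stages are testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
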