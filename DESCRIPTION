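Package: constrictaxis
Title: Constriction-Aligned Analysis of Microfluidic Neutrophil Chemotaxis
Version: 0.9.0
Authors@R:
    person("Constrictaxis", "Maintainers", email = "maintainers@constrictaxis.dev",
           role = c("aut", "cre"))
Description: Quantitative analysis of single-cell chemotaxis through a
    microfluidic constriction: device geometry and chemoattractant gradient
    modelling, constriction-aligned track kinematics (speed, confinement-ratio
    directionality, pre/post-constriction contrasts), shape-metric morphology
    and keratocyte-like classification, peri-constriction calcium trace
    analysis, cortical and nuclear-envelope intensity metrics, and a fully
    seeded synthetic-data generator (biased persistent random walk cohorts,
    calcium traces, rendered cell/nucleus label images) with stored ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
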