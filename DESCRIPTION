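Package: duplexform
Title: Sequence-Dependent DNA Structural Adaptation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how DNA duplexes adapt their structure upon
    minor-groove protein binding. Implements rigid base-pair and base-step
    parameter extraction with an exact inverse used by a duplex coordinate
    builder, deoxyribose pseudorotation analysis with North/South and
    anti/high-anti classification, groove-width and helical-axis curvature
    descriptors, protein-DNA contact statistics, metadynamics free-energy
    reconstruction from Gaussian hill deposits over a twist coordinate, and
    Hill-equation binding plus IRF-reconvolution fluorescence lifetime fits.
    A synthetic-data module generates ideal and perturbed A-/B-form duplex
    ensembles, geometric protein probes, hill deposits, titrations and
    photon-counting decays so that every analysis path is testable without
    molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
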