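Package: leafsettle
Title: Leaf Outline Morphometrics and Settling-Speed Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking two-dimensional leaf blade shape to sedimentation
    behaviour. Quantifies outline reflection symmetry (S) and lobedness (L),
    applies sinusoidal "digital mutations" to blade boundaries with a
    quantified modified-area fraction, generates comparison shapes (ideal
    forms, parametric leaves, random-walk outlines), estimates terminal
    settling speeds from centroid trajectories, and orchestrates a full
    shape-versus-settling study on synthetic data, including a calibrated
    phenomenological settling model for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    isoband,
    tibble,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    xml2
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    png,
    tiff,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
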