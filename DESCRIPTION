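Package: clotquant
Title: Turbidimetric and Morphometric Characterization of Fibrin Clots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fibrin clot structure and polymerization
    kinetics from microplate turbidity assays and fluorescence network images.
    Converts plate-reader absorbance to turbidity with near-infrared
    path-length correction, extracts clotting kinetics (lag phase, rate of
    clot formation, maximum turbidity), inverts multi-wavelength turbidity to
    fiber mass-length ratio and diameter with the Carr-Hermans and Yeromonahos
    rigid-rod scattering models, quantifies network morphology (percent area,
    pore size, fiber segment length) from binarized images, and fits
    Grubbs-screened simple and multiple linear regressions of each structural
    and kinetic parameter on fibrinogen and activator concentration. Includes
    a synthetic-data generator with known ground truth that emulates every
    input stream of the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
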