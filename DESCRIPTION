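Package: trapmass
Title: Segmentation-Free Cell Mass Measurement in Hydrodynamic Trap Arrays
    by Quantitative Phase Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the dry mass of single cells held in a rhombic array
    of hydrodynamic traps inside refractive-index-matched microfluidic
    channels, using differential phase contrast (DPC) quantitative phase
    imaging. Reconstructs optical-thickness maps from half-illumination DPC
    image pairs by Fourier least-squares integration, builds a periodic
    diamond trap mask from three measured anchor traps, integrates optical
    volume per trap, subtracts the mean empty-trap reference, and converts
    optical volume to picogram dry mass via the specific refractive
    increment. Includes repeatability statistics (spatial and temporal
    coefficient of variation, boxplot summaries), exponential growth-rate
    fitting, and a fully ground-truthed synthetic phase-image simulator so
    every pipeline stage can be validated without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
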