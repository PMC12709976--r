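Package: powderflow
Title: Microdynamic Powder Flowability Analysis from Flow-Pattern Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based characterisation of powder flowability at
    sub-200-mg sample scale. Computes the Flow Index (area fraction of a
    region of interest occupied by powder after flow through an orifice)
    and the Agglomeration Ratio (fraction of darker, cohesive pixels
    within the powder flow pattern) from backlit or frontlit grayscale
    flow-pattern images using Otsu thresholding with a histogram
    bimodality gate. Provides a four-band flow classification against
    microcrystalline-cellulose boundary materials, volume-weighted
    particle size distribution percentiles (Dv10/Dv50/Dv90) and span,
    and a seeded synthetic flow-pattern generator with per-pixel ground
    truth for validating the metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'psd.R'
    'classification.R'
    'imaging-core.R'
    'flow-metrics.R'
    'config.R'
    'batch.R'
    'imaging-io.R'
    'powderflow-package.R'
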