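Package: synaptrack
Title: Quantitative Live-Cell Imaging of MTOC Repositioning and
    Microtubule Motor Cluster Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify microtubule-organising centre (MTOC)
    repositioning and plus-end-tracking protein dynamics at the
    immunological synapse from TIRF/HILO live-cell movies. Implements
    dual-camera channel registration from a square-lattice calibration
    image, kymograph construction along traced microtubule paths with
    comet velocity (slope) and length (rise-to-baseline) measurement,
    refraction-corrected axial MTOC positioning with centre/periphery
    classification against a half-diameter ellipse, punctate cluster
    detection by size and contrast criteria with nearest-neighbour
    tracking and plus/minus/immobile motion classification,
    dual-colour track colocalisation statistics, and comparative-CT
    relative expression for qPCR readouts. A synthetic-movie module
    generates comet, cluster, defocus-series and calibration-lattice
    data with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
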