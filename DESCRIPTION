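Package: nitramap
Title: Nitrate Concentration Mapping from NIR Hyperspectral Leaf Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemometrics pipeline for non-destructive, spatially resolved
    quantification of nitrate in leaves from near-infrared (NIR)
    hyperspectral reflectance cubes. Provides ENVI cube input/output,
    white/dark reference reflectance calibration, frequency-domain
    stripe-noise removal for push-broom scanners, standard normal variate
    and gap-segment derivative spectral preprocessing, NIPALS partial least
    squares calibration with leave-one-out cross-validation, pixel-wise
    concentration mapping with leaf segmentation, storage-dynamics
    summaries (relative water and nitrate content), and a synthetic
    leaf-phantom generator so every pipeline stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
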