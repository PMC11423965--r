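Package: echotherm
Title: Ultrasound Texture Thermometry for Microwave Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tissue temperature during microwave ablation from
    B-mode ultrasound texture. Extracts the 104-feature IBSI radiomics
    battery (first-order, 2-D shape, GLCM, GLRLM, GLSZM, NGTDM, GLDM) from
    64x64 regions of interest around thermocouple positions, fits a random
    forest temperature regressor with Gini-importance feature selection,
    predicts per-pixel thermal maps by sliding-window regression, segments
    the 54 degree Celsius isotherm, and evaluates coagulation-zone area
    estimates against a gold standard with the error-ratio metric. A
    seeded speckle-image ablation simulator generates synthetic cases
    (temperature fields, frames, thermocouple logs, ground-truth areas)
    with the temperature-dependent texture drift the method relies on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
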