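Package: radiotex
Title: Texture Analysis of Dental Panoramic Radiographs
Version: 1.0.0
Authors@R: person("Radiotex", "Developers", email = "radiotex@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for discriminating radiolucent dental
    lesions (cysts, tumors, abscesses) from normal tissue on panoramic
    radiographs using texture features. Implements preprocessing (Gaussian
    smoothing, 3x3 median filtering, percentile contrast stretching),
    fixed-size region-of-interest extraction, three feature families
    (13 gray-level co-occurrence matrix features, 7 gray-level run-length
    matrix features, 5 wavelet-coefficient statistics from a separable Haar
    filter bank), a kernel maximum-margin classifier fitted by a
    deterministic SMO solver, and a full evaluation battery (confusion
    matrix, accuracy, Matthews correlation coefficient, sensitivity,
    specificity, positive predictive value, ROC/AUC). A seeded synthetic
    radiograph generator with class-specific Gaussian-random-field lesion
    textures makes every stage testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
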