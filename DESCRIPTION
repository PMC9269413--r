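Package: AlgaeSpectra
Title: Hyperspectral Discrimination of Intertidal Seaweed Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying intertidal macroalgae from field
    hyperspectral reflectance curves. Provides a SummarizedExperiment-based
    container for labelled spectral libraries, preprocessing (trimming to
    400-900 nm, replicate averaging, resampling to a 1-nm grid), extraction
    of fourteen derivative-spectroscopy variables (green peak, red valley,
    red/blue edge amplitudes, locations and areas, and RVI/NDVI indices),
    ANOVA-Tukey significance screening with accuracy-driven backward
    elimination, RBF-kernel support vector machine classification with grid
    search, a soft-voting SVM plus gradient-boosting fusion model, and
    micro/macro-averaged one-vs-rest ROC evaluation. Includes a synthetic
    spectrum generator anchored at published band-wise reflectance values of
    six seaweed species from three phyla, standing in for undeposited field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    pracma,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
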