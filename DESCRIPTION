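Package: organspectra
Title: Spectral Fingerprints, Variance Decomposition and Classification for Hyperspectral Organ Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative hyperspectral imaging of
    porcine organs. Provides preprocessing of hyperspectral datacubes
    (pixel-level l1 normalization, per-annotation median spectra), a
    per-organ spectral fingerprint atlas, per-wavelength linear mixed model
    decomposition of reflectance variance into organ, pig, angle, image and
    repetition components with parametric bootstrap confidence bands, a
    t-SNE embedding of annotation-level spectra with staged hyperparameter
    search, and a one-dimensional convolutional neural network organ
    classifier with leave-one-pig-out cross-validation and mean-logit
    ensembling. A synthetic-data generator reproduces the standardized
    acquisition protocol and the generative structure assumed by the mixed
    model so that every stage is testable without the original dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
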