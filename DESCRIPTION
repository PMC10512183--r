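Package: fibrospec
Title: FTIR Spectral Phenotyping of Cultured Fibroblasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for Fourier-transform infrared (FTIR)
    microspectroscopy of cultured cells: pre-processing of hyperspectral
    absorbance images (spectral-region excision, rubber-band baseline
    correction, k-means cell/background segmentation, spectral binning,
    EMSC-style scatter correction with a van de Hulst Mie extinction basis,
    Savitzky-Golay smoothing and second derivatives, vector normalization),
    band-region integration with ratio panels and one-way ANOVA / Tukey HSD
    group statistics, second-derivative peak-position analysis, and sparse
    partial least squares-discriminant analysis (sPLS-DA) with repeated
    cross-validated tuning and one-vs-rest AUROC evaluation. A synthetic
    cohort generator with known injected band effects provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    car,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
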