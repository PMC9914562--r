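Package: oliveauth
Title: Chemometric Authentication of Extra Virgin Olive Oil by Chained
    PLS-DA Classification and PLS Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale study of spectral authentication of extra
    virgin olive oil (EVOO) adulterated with cheaper edible oils. Simulates
    five measurement modalities (NIR hyperspectral imaging, FTIR, Raman,
    UV-Vis and GC-MS fatty-acid profiles) for a gravimetric binary-mixture
    design, implements NIPALS partial least squares (PLS) regression and
    PLS discriminant analysis from scratch as classed model objects, selects
    latent variables by a one-standard-error rule over repeated random
    10-fold partitions, and chains 13-class PLS-DA identification into
    per-adulterant PLS concentration prediction so that misclassification
    errors propagate into quantification. Includes reflectance calibration
    for hyperspectral cubes, standard normal variate and asymmetric
    least-squares preprocessing, calibration-curve quantification of fatty
    acid methyl esters, and the usual calibration diagnostics (RMSECV,
    RMSEP, R2, RPD) with confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
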