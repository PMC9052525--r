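Package: odspectra
Title: Univariate and Multivariate Classification of ELISA Absorbance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying ELISA absorbance spectra into ordinal
    severity classes, built around a comparison of single-wavelength optical
    density (OD 450 nm) thresholding against full-spectrum partial least
    squares discriminant analysis (PLS-DA, NIPALS) with standard normal
    variate, mean-centering and autoscaling preprocessing. Includes a
    Beer-Lambert synthetic spectrum generator with controllable baseline,
    scatter, noise and between-class overlap; CSV spectral input/output;
    stratified calibration/validation splitting; one-vs-rest confusion-matrix
    diagnostics (sensitivity, specificity, precision, accuracy); and a
    configuration-driven experiment runner. Motivated by gingival crevicular
    fluid DSPP biomarker assays for grading orthodontically induced root
    resorption.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
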