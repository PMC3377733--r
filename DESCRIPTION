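Package: ramanmix
Title: Spectral Unmixing of Raman Spectra with Variable Reference Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates analyte concentrations from Raman spectra when both
    the analyte and the background signatures vary from measurement to
    measurement. Implements classical least squares unmixing with an
    optional low-order polynomial background block (LS-qP), hybrid linear
    analysis (HLA), and a hybrid least-squares/principal-component
    estimator (HLP) in which each reference spectrum is allowed to flex
    along the principal components of its calibration set, with deviations
    penalized by the inverse eigenvalues and the fit solved by alternating
    pseudoinverse and Tikhonov-regularized least-squares steps. Includes
    Durbin-Watson and fractional-error diagnostics, a synthetic
    spectral-library generator, and a leave-one-out factorial simulation
    driver for comparing the three estimators.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
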