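Package: margindose
Title: Contour-Based Lung Dose Prediction for Breast Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ipsilateral lung dose-volume metrics (V20Gy(RBE),
    V5Gy(RBE)) for breast proton therapy from structure contours alone,
    before any treatment plan exists. A planning target volume (PTV) is
    expanded isotropically by a margin m using an anisotropic Euclidean
    distance transform; the fraction V(m) of the ipsilateral lung inside
    the expansion predicts the dose-volume metric V_D once the margin has
    been calibrated against planned dose by root-mean-square-error
    minimisation. Includes a dose-volume-histogram engine with
    prescription rescaling to a 50.4 Gy(RBE) reference, a cohort-growth
    convergence procedure for the calibration, a synthetic thoracic
    phantom factory with conformal and cold-spot dose fields, readers and
    writers for DICOM RT-STRUCT/RT-DOSE and NIfTI volumes, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
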