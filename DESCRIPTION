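Package: fmdiff
Title: Fractional Motion Model Analysis of Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anomalous-diffusion analysis of diffusion-weighted MRI
    with the fractional motion (FM) model. Builds multi-(Delta, G0)
    Stejskal-Tanner acquisition schemes and their b-values, evaluates the FM
    forward signal model parameterised by the Noah exponent (alpha), the Hurst
    exponent (H) and the anomalous diffusion coefficient, fits these
    parameters voxelwise by bounded nonlinear least squares alongside the
    conventional apparent diffusion coefficient (ADC), simulates digital
    phantom cohorts with Rician noise, and runs the group-discrimination
    statistics used in clinical diffusion studies: two-sample t-tests,
    ROC/AUC with Youden-index thresholds, logistic marker combination,
    Pearson partial correlation and Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
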