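Package: twophasedx
Title: Two-Phase Diagnostic Accuracy Analysis for Antenatal Depression Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating brief mental-health screening instruments under a
    two-phase (screen-stratified) verification design, as used to assess the Whooley
    questions and the Edinburgh Postnatal Depression Scale against a structured
    diagnostic interview in early pregnancy. Provides a synthetic-cohort generator
    with a binormal latent score model, stratified verification sampling with design
    weights, verification-bias-corrected weighted sensitivity, specificity, predictive
    values, likelihood ratios and prevalence with stratified bootstrap confidence
    intervals, covariate-adjusted ROC regression via placement values (ROC-GLM),
    predictive-mean-matching imputation of questionnaire items, inverse-probability
    weighting for missing gold-standard modules, and simulation-based design and
    power calculations for planned two-phase screening studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
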