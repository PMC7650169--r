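Package: atnpredict
Title: ATN Biomarker Classification and Risk-Factor Prediction for
    Preclinical Alzheimer's Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying cognitively healthy cohort participants
    into amyloid/tau/neurodegeneration (ATN) biomarker groups and for
    assessing how constitutional, cognitive and vascular risk factors
    predict group membership. Derives CSF biomarker cut-offs by
    two-component Gaussian mixture modelling (density-intersection or
    mean-plus-SD rules), applies decade-specific medial temporal atrophy
    thresholds, computes CAIDE and Framingham (general cardiovascular and
    stroke) composite risk scores from declarative point tables, fits
    covariate-adjusted binary and multinomial logistic association models
    with nested ROC/AUC model comparison, and ships a synthetic-cohort
    generator so the full pipeline can be exercised and tested without
    access-controlled study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    jsonlite
Config/testthat/edition: 3
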