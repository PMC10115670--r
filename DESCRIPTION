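Package: remsfs
Title: Fragility Score Computation and Fracture-Prediction Diagnostics for
    Radiofrequency Echographic Multi Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates radiofrequency (RF) ultrasound scans of lumbar spine and
    femoral neck with known ground truth, computes the REMS Fragility Score (FS)
    by spectral classification of RF segments against stratified reference models
    of fractured and non-fractured populations, and evaluates fracture-prediction
    performance with the standard diagnostic-accuracy toolkit: ROC curves and AUC,
    paired AUC comparison by the DeLong test, Youden-index cut-offs, confusion-table
    metrics (sensitivity, specificity, PPV, NPV, odds ratio with Woolf confidence
    intervals), covariate-adjusted ROC by residual linear fitting, and short-term
    precision as the root-mean-square coefficient of variation (RMS-CV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
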