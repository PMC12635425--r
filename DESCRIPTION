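Package: grscreen
Title: Two-Step Growth-Rate-Inhibition Drug Screening for Tumour Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for rapid chemosensitivity testing of
    patient-derived tumour organoids. Implements a two-step screen: a
    preliminary endpoint-viability screen at each drug's maximum plasma
    concentration (Cmax), followed by a secondary six-point titration scored
    with growth-rate-inhibition (GR) metrics computed from paired start/end
    ATP luminescence reads. Provides sigmoidal GR curve fitting with closed
    form GR50/GR100 solutions, normalized dose-response AUC and the AUCsum
    chemoresistance score for the paclitaxel + cisplatin regimen, a
    GR100/GRmax/Cmax decision tree for per-drug response calls, Cmax/GR100
    alternative-therapy ranking, concordance statistics against clinical
    response (confusion matrix, ROC AUC, Youden threshold), and a seeded
    generative model of plates and patient cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
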