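Package: aoprx
Title: Prescription Appropriateness Screening via Association Rule Mining
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Screens outpatient prescriptions for medications that are not
    explained by any diagnosis or co-medication on the same prescription.
    Disease-medication and medication-medication co-occurrence statistics
    (lift, the "Q value") are mined from prescription corpora, stratified by
    sex and 5-year age band; a prescription is substantiated when every
    medication has a positive association (Q above a threshold) with a
    co-listed diagnosis or medication. Includes one-shot federated merging of
    independently trained association models, an evaluation toolkit (enriched
    test-set construction, dual-rater adjudication with Cohen's kappa,
    confusion metrics with threshold sweeps, group comparisons, medication
    class tables), and a synthetic prescription generator with exact
    analytic lift oracles and ground-truth error labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
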