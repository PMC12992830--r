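Package: barriertox
Title: Barrier-Integrity Assays for Predicting Drug-Induced
    Gastrointestinal Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for predicting drug-induced gastrointestinal
    toxicity from in vitro epithelial barrier assays.  Raw
    transepithelial electrical resistance (TEER) and ATP-viability
    dose-response readouts are normalized to vehicle controls, fitted
    with a four-parameter logistic model, and summarized as IC15/IC50
    values (right-censored above the highest tested concentration) and
    percent reductions at the top dose.  Drugs are scored for clinical
    gastrointestinal toxicity from CTCAE severity grades and incidence
    categories, related to clinical exposure through margin-of-safety
    ratios (IC15 to Cmax), and classified by prespecified decision
    rules.  Diagnostic performance is evaluated with confusion metrics,
    Youden's J threshold sweeps, rank-based ROC AUC with DeLong
    confidence intervals and Mann-Whitney tests, and Pearson
    correlation analysis.  A 17-drug reference panel spanning
    cell-cycle inhibitors, tyrosine kinase inhibitors and NSAIDs is
    bundled, together with a synthetic dose-response generator for
    validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
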