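Package: glp1pv
Title: Disproportionality Signal Mining for GLP-1 Receptor Agonist
    Gastrointestinal Adverse Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pharmacovigilance signal-mining pipeline for spontaneous
    adverse-event reports on glucagon-like peptide-1 receptor agonists
    (exenatide, liraglutide, dulaglutide, semaglutide). Reads normalized
    report tables and a minimal FAERS-style ASCII dialect, applies
    study-style inclusion/exclusion/deduplication rules with an attrition
    log, builds drug-by-event 2x2 contingency tables against the pooled
    within-class comparator, and computes four disproportionality
    statistics: the reporting odds ratio (ROR), the proportional
    reporting ratio (PRR) with chi-square, two Bayesian confidence
    propagation neural network information-component variants (IC025),
    and age/sex-adjusted logistic regression. Ships published per-drug
    gastrointestinal case counts as a fixture for exact reproduction of
    printed signal tables, and a synthetic report generator with known
    reporting-rate multipliers for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
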