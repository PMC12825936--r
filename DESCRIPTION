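Package: cardiovigil
Title: Pharmacovigilance Signal Detection for Cardiac Adverse Events of
    Antibody-Drug Conjugates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for studying cardiac
    adverse events reported for antibody-drug conjugates in spontaneous
    reporting databases. Reads FAERS-style quarterly tables, deduplicates
    case versions, restricts to primary-suspect exposure, and screens
    cardiac-disorder preferred terms with reporting odds ratios (ROR) and
    Woolf confidence intervals, including subgroup, combination-therapy and
    per-cancer composite signals. Adds Table-1-style cohort description,
    Kaplan-Meier time-to-onset analysis with log-rank comparison, crude and
    adjusted logistic odds ratios for risk factors, and a transcriptome arm
    that converts counts to TPM, scores samples by single-sample gene-set
    enrichment (ssGSEA) and correlates per-cancer pathway activity with
    composite cardiac RORs by Spearman rank correlation. A seeded synthetic
    report and expression generator with known ground truth makes every
    stage testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
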