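Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance analysis pipeline for
    FAERS-style quarterly spontaneous-report extracts: ingestion of the
    five-table ASCII bundles (DEMO, DRUG, REAC, OUTC, INDI), case-version
    deduplication, suspect-role cohort construction for multi-drug
    regimens, reporting odds ratio (ROR) signal detection with Woolf
    confidence intervals, semi-quantitative clinical-priority scoring of
    significant signals, seriousness-stratified hypothesis testing, and
    cumulative-by-year ROR sensitivity analysis. Includes a synthetic
    spontaneous-report generator with injected drug-event associations at
    known true reporting odds ratios so every stage is testable without
    access to the real database. Ships reference inputs for the
    polatuzumab + bendamustine + rituximab (pola+BR) regimen analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
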