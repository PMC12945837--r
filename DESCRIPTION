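Package: pvscreen
Title: Disproportionality Signal Screening for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection from spontaneous
    case-report databases (FAERS-like extracts or flat tables): report ingestion
    and deduplication, drug-event two-by-two contingency tables, five
    disproportionality statistics with confidence or credibility bounds
    (reporting odds ratio, proportional reporting ratio with chi-square, the
    MHRA criterion, the BCPNN information component, and the EBGM relative
    reporting ratio), threshold-based signal screening at preferred-term and
    system-organ-class level, sex- and age-stratified screens, time-to-onset
    summaries, co-administration screens, and a synthetic spontaneous-report
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
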