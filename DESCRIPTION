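Package: rorsignal
Title: Reporting Odds Ratio Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Disproportionality analysis of spontaneous adverse-event report
    databases in the JADER (Japanese Adverse Drug Event Report) four-table
    layout. Integrates case, drug, event and history tables on the case key,
    applies suspected-drug and intravenous-route inclusion rules, computes
    per-drug reporting odds ratios with Woolf 95% confidence intervals, flags
    signals (CI lower bound above 1 with at least two cases), tests stratified
    signal-detection tables with Fisher's exact test, adjusts p-values with
    the Benjamini-Hochberg procedure, and emits volcano-plot coordinates. A
    seeded synthetic report generator plants known odds-scale effects so the
    whole pipeline is testable without access to the real database. Reference
    report counts for 25 antitumor antibodies and infusion reactions are
    bundled as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    withr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
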