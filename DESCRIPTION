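Package: wqwatch
Title: Water-Quality Forecasting, Grading and Pollution Early Warning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for surface-water-quality surveillance:
    seeded synthetic monitoring feeds, a crawl-clean-store ingestion loop
    with deduplication, lagged dependence-metric input selection (Pearson,
    cosine, distance correlation, maximal information coefficient),
    per-(watershed, sub-watershed, indicator) LSTM forecasting with a small
    built-in network engine, Nash-Sutcliffe and cross-correlation model
    evaluation with acceptability verdicts, water-quality class grading
    with attainment and category-proportion analyses, and automatic or
    manual pollution early warnings with Markdown reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
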