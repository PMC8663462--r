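Package: trialtables
Title: Parse and Classify Descriptive-Statistic Tables from Comparative Clinical Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining tables in the comparative clinical literature.
    Parses descriptive-statistic strings (mean +/- SD, median (IQR), n (%),
    and related micro-formats) into constituent statistics, detects
    measurement context (data elements, trial arms, time points) from header
    text, classifies table layouts into a 1x1/2x1/1x2 taxonomy of context
    dimensions, tags tables and articles against a reporting-practice
    hierarchy, summarizes tagged corpora with Wilson score confidence
    intervals and Boolean tag queries, and generates annotated synthetic
    randomized-controlled-trial tables with ground truth for benchmarking
    extraction pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
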