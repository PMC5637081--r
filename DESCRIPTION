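Package: hedgekit
Title: Development and Validation of Boolean Literature Search Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, evaluating and optimising Boolean literature
    search filters (hedges) against gold-standard-labelled corpora of
    bibliographic records. Reads MEDLINE tagged exports, parses and evaluates
    Ovid-syntax Boolean queries with field tags and truncation, computes 2x2
    contingency-table performance statistics (sensitivity, specificity,
    precision, number needed to read), performs single-term analysis and
    greedy OR-combination filter development with sensitivity- or
    specificity-maximising objectives, and generates labelled synthetic
    corpora with known term-occurrence structure for end-to-end validation.
    Ships published paramedic search filters with internal-consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
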