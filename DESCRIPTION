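Package: nhaneskit
Title: Retrieval, Decoding, Harmonization and Design-Based Analysis of
    Continuous-Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for working with NHANES-style
    continuous-survey releases: reads and writes SAS XPORT v5 transport
    files (including the IBM System/370 floating-point codec and missing
    value sentinels), parses NHANES-dialect HTML codebooks and table
    manifests, translates integer-coded variables to labelled categories,
    merges tables on the respondent sequence number within a cycle and
    aligns them across cycles with explicit compatibility guards, and
    produces design-based estimates (weighted means with Taylor-linearized
    standard errors under stratified, clustered, weighted sampling,
    including domain and grouped estimation). A synthetic fixture
    generator draws samples from a known finite population so every step,
    including estimator validity, is testable fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    xml2
Suggests:
    foreign,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
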