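Package: ibbfs
Title: Branch-and-Bound Search for Multi-SNP Genotype Combinations in
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects SNP-SNP interactions (statistical epistasis) in
    case-control genotype data by searching for multi-SNP genotype
    combinations that maximize the difference between matched control and
    case counts.  Implements an improved branch-and-bound search with
    level-wise feature selection (IBBFS), an exhaustive-search oracle,
    odds-ratio and classification statistics for grading combinations as
    high- or low-risk, seeded simulators for planted-pattern case-control
    data, and a command-line interface producing tabular reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
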