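Package: cnadriver
Title: Integrated Copy-Number and Expression Analysis for Amplicon Driver-Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments tumour copy-number marker profiles by circular binary
    segmentation with permutation inference, discovers recurrently gained
    regions with cytoband collapsing and germline copy-number-polymorphism
    subtraction, tests genes in those regions for dosage-driven differential
    expression with a self-implemented empirical-Bayes moderated t-statistic
    and copy-number/expression correlation, detects high-amplitude amplicons,
    and prioritises candidate driver genes by a two-branch cascade. Includes
    a synthetic tumour-cohort generator with planted amplicons, dosage
    slopes and germline polymorphisms so every stage is testable against
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
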