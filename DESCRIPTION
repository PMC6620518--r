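Package: assayval
Title: Analytical Verification of Continuous-Score Molecular Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analytical-verification computations used to
    validate continuous-score molecular diagnostic classifiers built on bulk
    RNA-seq: in-silico limit-of-detection by count mixing, interferent
    titration with four-parameter logistic fits, mixed-effect evaluation of
    technical factors, variance-component reproducibility analysis with
    block-bootstrap confidence intervals, and a noise-injection simulation
    that derives a tolerable-SD acceptance specification. Includes a
    synthetic-data generator and a transparent linear surrogate classifier so
    every stage is executable end-to-end without proprietary assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    DESeq2
Config/testthat/edition: 3
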