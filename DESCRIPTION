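Package: tpodkit
Title: Transcriptomic Point-of-Departure Estimation from Dose-Response
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving transcriptomic points of departure (tPODs)
    from multi-dose gene expression studies. Implements Williams trend
    prefiltering with permutation p-values, per-probeset benchmark-dose
    (BMD) modeling over the eight continuous dose-response model families
    (Hill, power, linear, quadratic polynomial and four exponential forms)
    with profile-likelihood confidence limits, gene set-based tPOD
    derivation under configurable minimum-enrichment filters, five
    distribution-based tPOD estimators (accumulation-curve knee, kernel
    density first mode, 5th/10th percentiles, 25th-lowest rank),
    structure-preserving gene-set randomization and transcriptome
    down-sampling experiments, and concordance metrics (absolute fold
    change, proportion within k-fold, log10 RMSD, sensitivity). A
    synthetic-data generator with analytically known true BMDs supports
    end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
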