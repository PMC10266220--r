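Package: methylMTS
Title: Methylation Treatment Scores from Dual-Cohort EWAS of Therapy Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for epigenome-wide association scanning of treatment
    effects on DNA methylation in case-control cohorts, construction of a
    weighted methylation treatment score (MTS) from replicated index CpGs,
    ROC/AUC discrimination, time-since-treatment modelling, reference-based
    immune-cell deconvolution with a cell-specific interaction scan,
    quartile-based genotype association using an exact Freeman-Halton test,
    hypergeometric overrepresentation analysis, and covariate sensitivity
    analysis. Includes a synthetic EPIC-array-like two-cohort data generator
    with planted effects so the full pipeline can be exercised and calibrated
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    pracma,
    fgsea,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
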