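Package: coxsnp
Title: Two-Track Selection of Prognostic SNPs in Clinical Time-to-Event Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies potentially prognostic single nucleotide polymorphisms
    (SNPs) in clinical cohorts with a time-to-event endpoint by combining two
    complementary tracks: covariate-adjusted univariate Cox proportional hazards
    screening with Benjamini-Hochberg false discovery rate control and a
    permutation-based min-P gene-region test, versus componentwise
    likelihood-based Cox boosting with cross-validated step selection.
    Selection stability is judged by inclusion frequencies over subsamples of
    size 0.632n. A block-correlated genotype and survival simulator and a
    type-I-error/power evaluation harness support method assessment, and a
    command line interface exposes the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
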