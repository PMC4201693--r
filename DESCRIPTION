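Package: treemwu
Title: Tree-Based Mann-Whitney Tests for Genome-Wide Gene-Gene
    Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects joint and epistatic association of SNPs with
    case-control disease status using Mann-Whitney U statistics computed
    on likelihood-ratio risk scores.  Implements the LRMW
    forward-selection risk-group tree with cross-validated depth and the
    TAMW bootstrap tree ensemble with out-of-bag likelihood-ratio
    averaging, together with permutation and train/test-split
    significance evaluation, PLINK 1 binary and text genotype input with
    bit-packed storage, and a retrospective case-control genotype
    simulator for null, epistatic-pair and many-weak-effect disease
    architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
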