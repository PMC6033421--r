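Package: globalscore
Title: Fast Score Tests for Case-Control GWAS with Missing Genotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Score tests for logistic-regression genome-wide association
    scans when genotypes are missing. Implements the conventional score
    test (per-SNP complete-case null fits) and two fast alternatives that
    reuse a single global null fit for every SNP, one of which applies an
    efficient-score correction that restores the power of the
    complete-case test. Also provides Wald, likelihood-ratio and
    median-imputation comparators, 1-df genotype and 2-df joint
    gene-environment tests, PLINK binary (.bed/.bim/.fam) input and
    PLINK-like output, and a Monte-Carlo laboratory for type-I-error
    calibration and power experiments under retrospective case-control
    sampling with missing-completely-at-random genotypes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
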