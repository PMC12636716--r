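Package: sgwas
Title: Spatial-Kernel Mixed-Model GWAS with Meta-Analysis, Heritability and
    Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association testing for binary or quantitative traits
    in which an individualized brain-region spatial-interaction kernel defines
    the covariance of a generalized linear mixed model random effect. Per-sample
    region-of-interest (ROI) imaging profiles are turned into Gaussian
    radial-basis-function kernel patterns, their cross-sample Pearson
    correlation matrix enters the model as the random-effect covariance, the
    null model is fitted by penalized quasi-likelihood with average-information
    REML, and each variant is tested with a score test. The package also
    provides inverse-variance fixed- and random-effects meta-analysis with
    Cochran's Q and DerSimonian-Laird between-study variance, GCTA-style
    genetic-relationship-matrix construction with REML SNP-heritability
    estimation, inverse-variance-weighted two-sample Mendelian randomization
    with leave-one-out sensitivity analysis, PLINK/VCF genotype input with
    standard quality-control filters, and a simulation module for benchmarking
    the spatial model against conventional per-SNP regression.
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
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    metafor,
    knitr
Config/testthat/edition: 3
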