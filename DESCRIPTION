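Package: polyGS
Title: Heritability, Regional Heritability Mapping and Genomic Selection
    for Polygenic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of quantitative
    traits from SNP dosage data and for genomic prediction. Implements
    VanRaden genomic relationship matrices, average-information REML for
    one or more genetic variance components with likelihood-ratio tests,
    mixed-linear-model association scans with a polygenic background,
    regional heritability mapping over sliding windows with
    leave-one-chromosome-out background kinship, and twelve statistical
    genomic-prediction models (rrBLUP, GBLUP, penalized regressions, the
    Bayesian alphabet via Gibbs sampling, and reproducing-kernel Hilbert
    space regression) behind one train/predict contract, evaluated by
    seeded k-fold cross-validation. A founder-haplotype mosaic simulator
    generates genotype panels and additive polygenic phenotypes with
    controlled heritability and regional variance enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    vcfR,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
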