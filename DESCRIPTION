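Package: asehpmm
Title: Allele-Specific eQTL Analysis with Hierarchical Poisson Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects allele-specific expression quantitative trait loci
    (aseQTLs) with a hierarchical Poisson mixed model (HPMM) that unifies
    allelic counts of heterozygous subjects and genotype-level counts of
    homozygous subjects in a single Poisson generalized linear mixed model
    with a subject-level and an observation-level random intercept and a
    library-size offset halved for allelic observations. Includes
    haplotype-based coding of non-exonic (GWAS) variants through phased
    exonic proxy SNPs, UMI-level quantification of allele-specific
    expression for droplet single-nucleus RNA-seq, a beta-binomial
    comparator restricted to heterozygous subjects, quality-control filters
    for imputed genotypes and allelic counts, a simulation framework for
    type-I-error and power studies, and LD-based interpretation of
    significant associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmmTMB,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
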