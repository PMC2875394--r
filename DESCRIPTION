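Package: paddymix
Title: Population Structure, Introgression and Admixture Mapping for Inbred SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of population structure and admixture in
    panels of inbred accessions genotyped at biallelic SNPs, as used in rice
    diversity studies. Implements maximum-likelihood admixture-model fitting
    (global ancestry proportions and subpopulation allele frequencies) by
    multi-restart EM, locus-specific ancestry via a linkage hidden Markov
    model with introgression-segment calling, unbiased (Weir) F_ST estimation
    per SNP, genome-wide and in physical windows, allele-sharing distances
    with neighbor-joining trees, admixture mapping by regression of phenotypes
    on local ancestry, and mixed-model association with a kinship random
    effect. Includes a Balding-Nichols panel simulator that generates
    genotypes, ancestry truth sets and phenotypes with the statistical
    structure these analyses assume, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml,
    jsonlite,
    vcfR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
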