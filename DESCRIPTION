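Package: admixqtl
Title: Local Versus Global Ancestry Adjustment in cis-eQTL Mapping for
    Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare local-ancestry (per-variant allele counts) and
    global-ancestry (genotype principal component) adjustment in cis-eQTL
    mapping of admixed cohorts. Includes a synthetic admixed-cohort generator
    (Balding-Nichols population allele frequencies, Poisson recombination
    tracts, Dirichlet admixture proportions, configurable cis-eQTL and
    ancestry-stratified expression effects, GWAS summary statistics),
    post-processing of per-site ancestry assignments into haplotype tracts and
    global-ancestry fractions, genotype PCA, variance partitioning of
    expression between the two ancestry representations, a dual-adjustment
    eQTL engine with lead-eVariant comparison, GWAS-eQTL colocalization
    scoring by approximate-Bayes-factor posteriors (PP0-PP4) and
    single-causal-variant fine-mapping (CLPP), and a screen for eVariants
    whose genotypes are confounded with local ancestry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
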