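Package: germburden
Title: Deleterious Mutation Burden in Conserved Seed Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying deleterious mutation burden in genebank
    germplasm from multi-sample genotype (VCF) and variant-annotation data.
    Implements site and genotype quality filtering, combined SIFT and GERP++
    rejected-substitution classification of deleterious SNPs with severity
    binning, per-sample heterozygous/homozygous/total burden estimators,
    minor-allele-frequency spectra, expression and RNA-integrity summaries,
    and an association battery (ordinary least squares regressions on
    conservation covariates, one-way ANOVA by origin, pairwise estimate
    screens, and paired cohort comparison). Includes a forward-in-time
    simulator of selfing germplasm under storage mutation, regeneration
    purging and drift for generating synthetic datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
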