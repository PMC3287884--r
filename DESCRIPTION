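Package: genesem
Title: Latent Gene Construct Structural Equation Models for Rare and Common Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage evaluation of aggregate rare- and common-variant effects on a
    quantitative trait. Stage 1 screens single-nucleotide polymorphisms with additive
    linear regression, indicator-coded rare-variant collapsing, principal-component
    stratification adjustment and Bonferroni-based gene selection. Stage 2 models each
    gene as a latent construct defined by its SNPs using a from-scratch maximum-likelihood
    structural equation modeling engine with nonnormality-robust (sandwich) standard
    errors and a mean-scaled test statistic, CFI/RMSEA/SRMR fit indices, and a
    standardized solution. Includes a multi-population synthetic genotype/phenotype
    generator with fixed-genotype phenotype replicates and a replicate-based
    parameter-recovery bias evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
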