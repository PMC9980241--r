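Package: scoremix
Title: Combining Published Polygenic Scores into Trait-Specific and
    Cross-Trait Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes published polygenic-score (PGS) weight files against a
    target genotype panel, computes per-individual scores, filters candidate
    scores analytically by the power of their association test, combines the
    retained scores into a single trait-specific or cross-trait score with a
    penalized (elastic-net) linear model, re-derives per-allele SNP effects for
    the combined score, and evaluates clinical utility via category-free net
    reclassification improvement, incremental AUC and odds ratios. Includes a
    simulation engine for genotypes, correlated SNP-effect vectors and
    phenotypes supporting training-size and heritability experiments on
    fully synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
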