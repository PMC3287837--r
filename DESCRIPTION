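Package: rvcollapse
Title: Gene-Based Rare-Variant Collapsing Tests for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Alex", "Moreau", email = "alex.moreau@example.org", role = c("aut", "cre"))
Description: Gene-based association testing of quantitative traits against
    rare genetic variants. Implements three rare-variant collapsing scores
    (carrier indicator, minor-allele count, and a data-adaptive sum that
    flips the coding of variants with nominally negative effects), combined
    with three strategies for common variants in the same gene region (rare
    score alone, combined multivariate and collapsing with all common
    variants, and LASSO selection of common variants with the rare score and
    covariates forced in). Association is assessed with a nested-model F
    statistic adjusted for covariates. Includes an evaluation framework that
    pools null-trait results into an empirical null distribution to derive
    significance thresholds, type I error, and per-gene power, a
    Freedman-Lane style permutation test for the data-adaptive score, and a
    synthetic genotype/covariate/trait simulator emulating an exome panel of
    697 unrelated subjects from seven populations with 200 phenotype
    replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
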