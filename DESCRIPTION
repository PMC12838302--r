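Package: alphamix
Title: Mixture-Frequency Models of MAF-Dependent Genetic Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how per-allele effect-size variance and the
    probability that a variant is non-synonymous depend on a weighted mixture of
    African and European minor allele frequency (MAF). Provides a generative
    simulator for correlated two-population allele-frequency panels, sparse
    MAF-dependent causal architectures and GWAS summary statistics; bivariate MAF
    binning; a simplified stratified LD-score regression stage yielding bin-wise
    per-allele effect-size variance estimates; a generalized-method-of-moments
    estimator of the mixture weight and MAF-dependence exponent with
    block-jackknife uncertainty and random-effects meta-analysis; and
    profile-likelihood estimation of the mixture weight for non-synonymous
    status, including non-nested model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
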