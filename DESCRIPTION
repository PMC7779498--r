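Package: vocalconv
Title: Vocal Convergence Analysis for Multi-Level Animal Societies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test for vocal convergence in nested animal societies
    from call-level acoustic features and microsatellite genotypes. Implements
    stepwise discriminant function analysis with Wilks'-lambda entry/removal,
    pairwise-F acoustic dissimilarity (log-transformed), a permuted DFA that
    balances unequal call contributions, locus screening (exact
    Hardy-Weinberg test, null-allele heterozygote-deficit estimator), the
    Wang moment estimator of pairwise relatedness, Mantel and categorical
    Mantel tests with free and block-restricted permutation schemes, a
    relatedness-quartile contrast, and Cohen's d effect sizes. A hierarchical
    synthetic-data generator (gang/party/individual variance components for
    calls; pedigree-derived genotypes with within-party sibships) makes the
    whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
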