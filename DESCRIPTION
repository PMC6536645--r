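Package: mrpcnet
Title: Causal Network Learning for eQTL-Gene Sets via Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns causal networks among genetic variants and molecular
    phenotypes (such as gene expression) by combining PC-style constraint-based
    graph learning with the principle of Mendelian randomization: genotype
    alleles are randomly assigned in a population, so variant-to-phenotype
    edges can be oriented a priori and used to anchor causal directions among
    phenotypes. Conditional-independence testing uses partial correlations
    with Fisher's z transformation; the family of sequential tests is
    controlled at a target false discovery rate with the online LOND
    procedure; an outlier-robust, beta-weighted correlation estimator can
    replace Pearson correlation when contamination is suspected. The package
    also ships the linear-Gaussian genotype/phenotype simulator and the
    direction-aware recall/precision scoring used to benchmark such learners,
    plus bootstrap edge-probability estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
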