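Package: adaptrepeat
Title: Quantifying Constraints on the Repeatability of Genetic Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for measuring how strongly constraints limit the
    diversity of genetic routes to adaptation, from gene-by-lineage matrices
    of binary or continuous adaptation evidence. Implements probability-scaled
    repeatability effect sizes based on the hypergeometric distribution
    (C_hyper) and on a permutation chi-square goodness-of-fit test (C_chisq),
    exact hypergeometric overlap p-values, maximum-likelihood estimation of
    the effective number of genes available to adaptation from a
    binomial-mixture model of lineage occupancy, corrections for incomplete
    sampling of the gene universe, reference similarity indices (Jaccard,
    proportional similarity), and generators of synthetic test data including
    a two-patch Wright-Fisher migration-selection-balance simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
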