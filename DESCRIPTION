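Package: rvlocus
Title: Locus-Wide Association Tests for Sequence Data with Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Case-control association tests for resequenced loci containing
    rare variants, built on nonnegative single-variant Cochran-Armitage trend
    statistics: a Bonferroni-corrected maximum test and efficient permutation
    tests on the maximum or sum of trend chi-square statistics, together with
    two widely used pooling tests (the Combined Multivariate and Collapsing
    test via Hotelling's T-squared with a g2 generalized inverse, and a
    modified Weighted Sum Statistic).  Also provides an analytic power model
    for a two-variant locus under linkage disequilibrium, a neutral coalescent
    simulator of haplotype populations, logistic disease models, case-control
    rejection sampling, a Markov-chain model of randomly missing genotypes,
    and drivers for type I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
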