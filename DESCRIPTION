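Package: coexsig
Title: Coexpression-Signature Meta-Profiling of Tumor Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives a differential-expression signature from a two-condition
    cell-line experiment with an empirical-Bayes moderated t-statistic, ranks
    the genes of a multi-tumor expression compendium by Pearson distance to a
    designated reference gene, scores the signature's positional enrichment
    near the top of that ranking with a running-sum Kolmogorov-Smirnov
    statistic, and assesses significance with a permutation null. Includes
    readers and writers for the GCT and CLS formats, the classical microarray
    variation and compendium intensity filters, cross-platform gene-symbol
    mapping, and synthetic-data generators that plant known differential and
    coexpression structure for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
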