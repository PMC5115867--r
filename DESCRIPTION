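Package: edsnet
Title: Cross-Species Co-Expression Modules and Duplicate Retention in
    Herbivory-Induced Early Defense Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying herbivory-elicited early-defense-signaling
    co-expression modules across closely related plant species and for testing
    whether duplicates derived from whole-genome multiplication are
    preferentially retained in such modules. Implements TMM-FPKM normalization,
    expression filtering, an exact negative-binomial differential-expression
    test, empirical-Bayes cross-species batch adjustment, weighted co-expression
    networks with topological overlap, module detection and preservation
    Z-statistics, Markov clustering of similarity graphs, gene-tree/species-tree
    LCA reconciliation with support-filtered duplication dating, NG86 Ka/Ks
    estimation, and the retention-enrichment statistics (odds ratios, exact
    binomial and chi-square tests). Ships a synthetic-data generator that
    emulates the full study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    ape,
    edgeR,
    sva,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
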