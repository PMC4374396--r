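Package: famshift
Title: Birth-Death Models and Simulation Tests for Clade-Specific Gene
    Family Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether a gene family has expanded in a focal
    clade beyond the expectation of neutral duplication and loss. Fits
    linear birth-death models of gene copy-number evolution on a dated
    species tree, with optional clade-specific rate shifts, and compares
    nested models by likelihood-ratio tests with chi-square or simulated
    null p-values. Reconciles gene trees against the species tree by LCA
    mapping to count per-branch duplications and losses, simulates gene
    ("guest") trees along the species phylogeny to build empirical null
    distributions of clade duplication, loss and net-expansion counts,
    and reconstructs ancestral family sizes by linear-cost parsimony or
    marginal posterior modes. Includes generators for synthetic
    chronograms and count matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
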