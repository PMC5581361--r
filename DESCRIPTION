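Package: hgtindex
Title: HGT-Index Computation by Duplication-Transfer-Loss Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects horizontal gene transfer (HGT) by reconciling orthologous
    gene trees against a rooted reference species tree under the undated
    duplication-transfer-loss (DTL) maximum-parsimony model, and summarises
    each gene set with an HGT-index, the number of inferred transfer events
    divided by the number of member genomes. Includes unrooted gene-tree
    rooting by exhaustive edge enumeration, gene-set exclusion filters and
    HGT-gene / HGT-free classification, Pfam majority-rule assignment and GO
    biological-process keyword counts, and a synthetic tree simulator that
    implants a known number of transfer-like subtree-prune-and-regraft edits
    so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
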