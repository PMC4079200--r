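Package: retroclock
Title: Dating, Phylogeny and Horizontal-Transfer Analysis of LTR Retrotransposon Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the evolutionary analysis of centromeric and other
    long-terminal-repeat (LTR) retrotransposon families: structural discovery of
    full-length elements with target-site-duplication validation, insertion dating
    from 5'/3' LTR divergence under the Kimura 2-parameter model, lineage
    divergence dating from Nei-Gojobori synonymous distances, neighbor-joining
    phylogenies with bootstrap support under the Tamura 3-parameter model,
    sliding-window similarity profiles with recombination breakpoint and mosaic
    subdomain typing, and horizontal-transfer detection by box-plot outlier
    analysis of element versus host divergence times. A forward simulator of
    element families evolving along a host species tree provides ground-truthed
    synthetic data for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
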