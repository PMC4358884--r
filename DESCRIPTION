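Package: pathprio
Title: Hybrid Candidate-Gene Prioritization on Weighted Protein
    Interaction Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate genes for a biological process from a
    confidence-weighted protein-protein interaction network and a set of
    known (seed) genes.  The core method counts, for every protein, the
    number of seed-pair shortest paths on which it lies as an inner node
    (a path-count betweenness), filters these shortest-path genes with a
    permutation false-discovery rate, and then applies sequence-similarity
    and interaction-confidence filters against the seed set.  Comparator
    methods (random walk with restart, similarity-only and
    interaction-only classifiers), a leave-one-out jackknife evaluation,
    experimental-evidence statistics for the protein interactions on the
    selected paths, and a synthetic-network generator with planted bridge
    genes are included, so the whole pipeline can be exercised without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
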