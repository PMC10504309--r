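Package: dsrevo
Title: Comparative Genomics and Phylogenetics of the Dissimilatory Sulfite
    Reduction Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for reconstructing the evolutionary
    history of the dissimilatory sulfite/sulfate reduction (Dsr) pathway from
    annotated prokaryotic genomes: decoy-aware protein family assignment with
    identity and E-value filtering, identity-graph Markov clustering for
    redundancy reduction, progressive multiple alignment with gap-threshold
    trimming, distance-based tree inference with column-bootstrap supports,
    minimal-ancestor-deviation and outgroup rooting, gene-neighborhood synteny
    extraction, and presence/absence pathway genotyping.  A bundled
    synthetic-genome simulator with planted gene clusters, decoy homolog
    families, genome incompleteness, and lateral gene transfer events provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
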