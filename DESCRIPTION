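Package: lintree
Title: Maximum-Parsimony Phylogeny Inference for CRISPR/Cas9 Lineage Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing single-cell phylogenies from CRISPR/Cas9
    lineage-tracing character data. Implements a greedy perfect-phylogeny
    heuristic, a Steiner-tree integer linear programming solver over an
    inferred potential graph, and a hybrid of the two; a forward simulator of
    lineage-tracing experiments (indel state distributions, dropout,
    subsampling, base-editor and phased-recorder presets); closed-form theory
    for parallel evolution of indel mutations; evaluation statistics
    (parsimony, depth-stratified triplets correct, meta purity, mean majority
    vote, allelic and phylogenetic distances, character bootstrapping); and
    allele-table utilities (indel prior estimation, mutation-rate estimation,
    clone calling, doublet detection).
License: MIT
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
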