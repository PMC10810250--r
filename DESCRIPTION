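Package: ccdbg
Title: Colored Compacted de Bruijn Graph Indexing and Pseudoalignment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a self-contained colored compacted de Bruijn graph (ccdBG)
    index that maps any k-mer of a reference collection to its color, the set
    of references containing it. The index composes an order-preserving k-mer
    dictionary over color-sorted unitigs, a one-bit-per-unitig rank structure
    mapping unitigs to color ids, and a density-routed hybrid compressed
    inverted index over the distinct colors (Elias-delta gap coding for sparse
    sets, a complemented encoding for very dense sets, characteristic
    bit-vectors otherwise, with an Elias-Fano offset directory). On top of the
    index, four pseudoalignment algorithms are provided (full-intersection,
    threshold-union, and two skipping heuristics) together with a two-pass
    multi-query optimization, a bacterial pangenome fixture generator, a read
    simulator, and density-decile compression statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Sequencing, Alignment, DataRepresentation, Metagenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
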