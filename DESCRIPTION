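Package: recold
Title: Sequence-Based Comparison of T-Cell Receptor Repertoires in Low Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies inter-sample differences among T-cell receptor CDR3
    repertoires from sequence information alone. Pairwise Smith-Waterman local
    alignment scores over the unique sequences of all samples are converted into
    a length-adjusted dissimilarity matrix, embedded into a low-dimensional
    space (SMACOF multidimensional scaling, ISOMAP, spectral embedding, or
    t-SNE), and each sample's sequence distribution is estimated on a shared
    grid by exponential-kernel density estimation with cross-validated
    bandwidth. Pairwise repertoire differences are measured by the
    Jensen-Shannon divergence, decomposed into a per-bin local divergence map
    that identifies the sequences driving each pairwise difference, organised
    into a dendrogram by Ward clustering, and tested for significance by a
    bootstrap of the estimated densities. A synthetic motif-family repertoire
    generator makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    igraph,
    vegan,
    optparse
Config/testthat/edition: 3
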