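Package: pvpanno
Title: Phage Virion Protein Identification and Functional Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of phage virion proteins (PVPs) and their
    seven-way functional annotation (portal, major/minor capsid,
    major/minor tail, baseplate, tail fiber) from protein sequences.
    Provides per-protein embeddings by mean pooling of residue-level
    vectors behind a pluggable embedder backend, a small one-dimensional
    convolutional classifier trained with an asymmetric loss that
    counteracts class imbalance, homology-aware benchmark splitting
    protocols (by release date, by pairwise identity-times-coverage, and
    by class-imbalance ratio), keyword-based labeling of annotation
    lines, and a two-stage genome annotation pipeline producing TSV and
    GFF3 reports, including extraction of tail-fiber candidates for
    downstream host prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics
Config/testthat/edition: 3
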