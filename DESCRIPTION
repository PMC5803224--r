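Package: foramotu
Title: Metabarcoding Inference for Planktonic Foraminifera
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a complete amplicon metabarcoding
    inference chain for planktonic foraminifera: demultiplexing and primer
    filtering of tagged pyrosequencing reads, de-novo two-parent chimera
    screening, single-linkage clustering of amplicons at a local edit-distance
    threshold into molecular operational taxonomic units (MOTUs),
    global-alignment taxonomic assignment against annotated reference
    databases, K80-distance barcode-gap species delimitation anchored to
    reference genetic types and morphospecies, meta-reference reassignment of
    the full dataset, and ecological summaries (rarefaction, occurrence and
    clade composition).  A synthetic amplicon-community generator with full
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    graphics,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
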