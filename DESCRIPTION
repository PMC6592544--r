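Package: tcrenrich
Title: Detecting Antigen-Driven TCR Clonotype Clusters from Single Repertoire Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies T cell receptor (TCR) clonotypes involved in an ongoing
    immune response from a single repertoire sequencing (RepSeq) snapshot. For
    each amino-acid CDR3 sequence the observed number of sequence neighbors
    (same VJ class, at most one amino-acid mismatch) is compared against a
    Poisson null expectation derived from a generative V(D)J recombination
    model, with Benjamini-Hochberg control of the false discovery rate. Includes
    an abundance-aware variant of the test based on convolutions of the
    empirical log read-count distribution, a naive neighbor-density baseline, a
    position-weight-matrix selection model with selection-logo output, hit-graph
    reporting, and a fully synthetic repertoire simulator with planted
    convergent-response clusters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
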