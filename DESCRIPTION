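Package: localign
Title: Local Alignment of Cross-Species Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds local alignments between two protein-protein interaction
    networks seeded by ortholog pairs. Constructs an alignment graph over
    cross-species protein pairs with a seven-parameter match/mismatch/gap
    edge-weighting scheme, mines conserved modules with a from-scratch
    Markov clustering (MCL) implementation, scores module functional
    coherence with Gene Ontology semantic-similarity measures (Resnik, Lin,
    Jiang, Wang) aggregated by best-match average, and assesses significance
    against size-matched random alignments. Includes generators for paired
    synthetic networks with planted conserved modules and toy ontologies
    with controlled annotation coherence, so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
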