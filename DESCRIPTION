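Package: kgfuse
Title: Entity Fusion for Disease-Centred Medical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges knowledge-graph triples extracted from heterogeneous
    medical sources (electronic medical records versus curated health
    websites) into a single disease-centred graph. Provides schema-validated
    triple input/output, translational knowledge-graph embeddings (TransE,
    TransH, TransR) trained with margin ranking loss and type-constrained
    negative sampling, string and structural similarity features
    (character Jaccard, character-bigram cosine, shared-tail counts),
    classifier-based tail- and head-entity alignment with union-find merge
    closure, a synthetic two-source benchmark generator with ground-truth
    alignment labels, ICD code annotation, and export to Neo4j bulk-import
    CSV and RDF N-Triples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    stringi,
    withr,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
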