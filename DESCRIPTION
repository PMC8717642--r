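Package: docrel
Title: Document-Level Relation Extraction with Edge-Oriented Document
    Graphs and External Knowledge
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for document-level biomedical relation extraction
    using an edge-oriented graph neural network.  Documents are parsed
    from PubTator-style annotated abstracts, segmented into a
    chapter/sentence hierarchy, and turned into typed graphs over
    mention, entity, sentence, chapter and document nodes.  The graph
    is optionally augmented with knowledge nodes carrying external
    entity representations learned from a knowledge-graph triple store
    (TransE, RESCAL or a graph-attention encoder) or from entity
    description text (a distributed-memory paragraph embedder or an
    end-to-end recurrent encoder).  Entity pairs are classified from
    long-path representations built by iterative walk aggregation over
    edge representations, trained with a combination of cross-entropy
    and a differentiable soft F-measure loss.  Includes a synthetic
    corpus and knowledge-graph generator with planted relational
    structure for controlled benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
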