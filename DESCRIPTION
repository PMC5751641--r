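Package: bioevent
Title: Biomedical Event Extraction with Multiple Distributed Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for biomedical event extraction from
    BioNLP Shared Task standoff corpora. Triggers are identified by a
    feed-forward network over concatenated context, topic, part-of-speech
    and dependency-distance embeddings; arguments are detected by a
    convolutional network over dependency-path feature matrices; predicted
    relations are assembled into events under a configurable schema and
    scored with approximate span and recursive event matching. Includes
    readers and writers for standoff (.txt/.a1/.a2) and CoNLL-X formats
    and a seeded synthetic corpus generator with planted, learnable signal
    so the whole pipeline can be trained and evaluated without external
    corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
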