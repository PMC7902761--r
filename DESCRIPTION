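Package: cidre
Title: Document-Level Chemical-Induced Disease Relation Extraction with
    Gated Graph Convolutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts chemical-induced disease (CID) relations between
    normalized MeSH concepts from annotated biomedical abstracts in
    PubTator format.  Documents are encoded sentence-by-sentence with a
    bidirectional LSTM; mention, entity and sentence nodes are assembled
    into a heterogeneous document graph; stacked graph-convolution layers
    with a sigmoid gating mechanism (mitigating over-smoothing) aggregate
    cross-sentence evidence; and a bilinear softmax classifier scores every
    chemical x disease concept pair.  Includes a synthetic-corpus generator
    with planted cue-determined relations, an intra-/inter-sentence
    evaluation harness, ablation utilities and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
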