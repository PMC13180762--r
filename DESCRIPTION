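Package: hypertrail
Title: Temporal Hypergraph Contrastive Learning for Future Hyperedge Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models year-stamped sets of biomedical concepts (one hyperedge per
    article) as a temporal hypergraph and predicts which concept sets will
    co-occur in future publications. For each target hyperedge a temporally
    constrained random walk assembles a trail of concept-overlapping
    predecessor hyperedges; hyperedges are tokenized from local hypergraph
    convolutions, random-walk positional encodings on the bipartite expansion,
    and learnable cosine time encodings, then contextualized by a causally
    masked transformer. Training combines a binary cross-entropy objective
    over hard (partial concept replacement) and global negatives with a
    time-anchored margin contrastive loss. Includes a synthetic generator of
    temporal hypergraphs with planted lineage evolution, a trail-aware
    evaluation protocol (AUC, accuracy, precision, F1, average precision),
    and consistency/ablation reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
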