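Package: pgxlinker
Title: Pharmacogene Suggestion from Gene-Drug-Phenotype Linked Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate pharmacogene gene-drug pairs by learning from a
    typed gene-drug-phenotype linked-data graph. Builds and manipulates the
    graph (N-Triples input, cross-source equivalence mapping, pair-node
    augmentation, edge-direction normalisation), constructs labeled pair sets
    from variant-level evidence annotations with exclusion-aware negative
    sampling, derives features along two routes (a multi-instance path-feature
    matrix for a random forest, and substructure-count graph kernels - bag of
    labels, walks, Weisfeiler-Lehman style subtrees - for a support vector
    machine on a precomputed kernel), evaluates both with repeated stratified
    nested cross-validation, and ranks and intersects the resulting candidate
    lists. A seeded synthetic linked-data generator with a planted association
    signal makes every stage testable without access to licensed sources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    kernlab,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
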