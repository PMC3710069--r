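Package: smrwalign
Title: Probabilistic Multiple Alignment of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aligns two or more protein-protein interaction networks by
    estimating probabilistic node correspondence scores with a semi-Markov
    random walk on the product graph, sharpening the pairwise alignment
    probabilities with intra-network and cross-network probabilistic
    consistency transformations, and greedily constructing a maximum
    expected accuracy multiple alignment under coherence and cardinality
    constraints. Includes the standard evaluation measures for multiple
    network alignment (specificity, correct nodes, mean normalized entropy,
    conserved interactions, coverage, sensitivity) and a synthetic
    network-family generator based on duplication-driven growth models
    (DMC, DMR, CG) with known orthology, so the whole pipeline can be
    exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
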