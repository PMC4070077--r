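Package: netprio
Title: Network-Based Disease-Gene Prioritization with Kernel Score
    Functions and Multi-Network Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Ranks candidate disease genes over weighted functional gene
    networks. Implements q-step random-walk graph kernels with the
    kernelized score functions S_NN, S_kNN and S_AV, random walk and
    random walk with restart label propagation, and a guilt-by-association
    baseline. Multiple heterogeneous networks over a shared gene universe
    can be fused by unweighted operators (average, per-edge average,
    maximum, drastic or soft minimum) or by AUC-weighted averaging with
    per-disease or class-averaged network weights estimated by internal
    cross-validation. Ships the full evaluation protocol (node-wise
    k-fold cross-validation, AUC, precision at recall, label-shuffling
    permutation test, ECDF-percentile candidate analysis), bipartite
    projection operators, network pre-processing, readers and writers for
    edge lists, bipartite tables, GMT gene sets and rankings, a synthetic
    planted-module benchmark generator, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
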