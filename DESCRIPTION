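Package: trihetnet
Title: Triple-Layer Heterogeneous Network Propagation for Small
    Molecule-miRNA Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts associations between small molecules (SMs) and
    microRNAs by information propagation on a three-layer heterogeneous
    network (small molecule, miRNA, disease) built from known SM-miRNA
    and miRNA-disease associations and integrated intra-layer
    similarities.  Implements Jaccard annotation-profile similarity,
    two MeSH-DAG disease semantic similarity models, the Gaussian
    interaction profile kernel, weighted similarity integration with
    per-cell coverage renormalisation, symmetric degree normalisation,
    the iterative two-matrix propagation update with L1 convergence
    control, a network-based inference (NBI) resource-allocation
    baseline, and a full cross-validation suite (global and local
    leave-one-out, repeated k-fold, random-association control) with
    rank-percentile ROC/AUC.  A synthetic triple-layer data generator
    with planted block structure makes every component testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
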