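Package: pathDRP
Title: Pathway-Based Drug Response Prediction with Explainable Neural Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug sensitivity (log-transformed IC50) of cancer cell
    lines from pathway-level features and explains the predictions. Five
    feature blocks are engineered per drug-cell pair: Morgan fingerprints of
    the drug structure (CHEM), network-based pathway enrichment of expanded
    drug targets (DG-Net), single-sample GSEA of gene expression (EXP), and
    expression-weighted network pathway enrichment of somatic mutations
    (MUT-Net) and copy-number-altered genes (CNV-Net). Network enrichment
    uses random walk with restart over a weighted protein-protein interaction
    network with permutation z-score normalization. A fully connected neural
    network with early stopping regresses the response; evaluation drivers
    cover repeated k-fold, leave-one-drug-out and leave-one-cell-out splits,
    plus a cross-dataset error floor and a Laplace residual diagnostic.
    Sampling-based Shapley values attribute predictions to pathways. A
    synthetic data generator with a planted pathway-response effect makes the
    full pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Matrix,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluation.R'
    'explain.R'
    'features.R'
    'fingerprints.R'
    'fnn.R'
    'io.R'
    'netpea.R'
    'rwr.R'
    'ssgsea.R'
    'synthetic.R'
    'targets.R'
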