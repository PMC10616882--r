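Package: decoyQA
Title: Single-Model Protein Decoy Quality Assessment with Dual-Graph
    Convolutions and a Score-Dependent Epsilon-Insensitive Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the accuracy of computationally predicted protein
    structures (decoys) without access to the native structure.  A graph
    convolutional network operating on dual atom-level and residue-level
    nearest-neighbour graphs predicts per-residue and global GDT-TS and
    lDDT scores; training uses an epsilon-insensitive regression loss
    whose tube width is a step function of the true score, so that
    high-quality decoys are fitted tightly while poor decoys are only
    loosely constrained.  Also provides reference implementations of the
    lDDT and GDT-TS scoring functions, k-nearest-neighbour graph
    construction with a same-residue/cross-residue edge partition, a
    synthetic decoy generator for desk-scale training and benchmarking,
    and the standard global and local evaluation metrics (Pearson,
    Spearman, per-target correlation, RMSE, AUROC, AUPR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
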