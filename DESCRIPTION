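Package: topscreen
Title: Ligand-Based Virtual Screening with Random Forests and Topological Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for ligand-based virtual screening of small-molecule
    inhibitor candidates (developed around human topoisomerase I inhibition).
    Reads and standardizes molecules from SMILES and SDF, computes a versioned
    registry of 2D/3D molecular descriptors (simple properties, Wiener and
    centric indices, Kier-Hall connectivity chi and kappa shape indices,
    electrotopological-state sums, grid-based rugosity), trains four
    from-scratch classifiers (random forest with out-of-bag tuning and
    permutation importance, RBF support vector machine, k-nearest neighbours,
    C4.5-style decision tree), evaluates them with confusion-matrix statistics
    (SE, SP, Q, MCC) and ROC/AUC, scores structural diversity of compound sets
    by mean pairwise Tanimoto dissimilarity, and screens compound libraries
    with a relative-probability-score cutoff followed by an imported
    docking-energy filter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    kernlab,
    rpart,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
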