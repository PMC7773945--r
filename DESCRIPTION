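Package: raspdplus
Title: Pose-Invariant Physicochemical Descriptors and Ensemble Learners
    for Protein-Ligand Binding Free Energy Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fast, docking-free estimation of protein-ligand binding free
    energies from six ligand descriptors (molecular weight, hydrogen-bond
    donor and acceptor counts, Wildman-Crippen logP and molar refractivity,
    Wiener topological index) and fourteen binding-pocket descriptors derived
    from residues and atoms selected by spheres sized from the ligand's
    maximum extent (maxD). Models are trained with a nested cross-validation
    ensemble of classical learners (linear regression, k-nearest neighbours,
    linear and RBF support vector regression, random and extremely random
    forests, and a small feed-forward network), with permutation feature
    importance, feature-ablation retraining, and active/decoy enrichment
    analysis for virtual screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    e1071,
    randomForest,
    ranger,
    caret,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
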