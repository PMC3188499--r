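Package: caaxbind
Title: Structure-Based Prediction of Farnesyltransferase Cxxx Substrate
    Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts which C-terminal Cxxx tetrapeptides can bind protein
    farnesyltransferase (FTase) by threading candidate sequences onto a
    template peptide backbone taken from a receptor-peptide complex, packing
    side chains from a rotamer library, minimizing the pose in torsion space
    under harmonic distance constraints that preserve the conserved binding
    geometry (two anchor hydrogen bonds and the cysteine-thiol coordination
    site), and scoring the minimized pose with a decomposable energy model.
    Includes sequence-space enumeration, proteome scanning for C-terminal
    Cxxx motifs, position frequency matrices, ROC/AUC evaluation of labeled
    peptide sets, threshold calibration, and a synthetic toy-template
    generator so the whole pipeline is testable without external structure
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
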