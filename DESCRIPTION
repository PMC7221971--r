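Package: geppi
Title: Protein-Protein Interaction Prediction from Graph-Energy Sequence
    Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions from amino-acid sequence
    alone. Each protein is encoded by two sliding-window graph-energy
    profiles -- a physicochemical profile built from a 0/1 substitution
    matrix over an isoelectric-point ordering of the residues, and a contact
    profile built from a real-valued amino-acid contact-energy matrix --
    together with the 400-dimensional dipeptide composition. Fused
    descriptors are reduced by principal component analysis and protein
    pairs are classified with a weighted sparse representation classifier
    (Gaussian-kernel weighted L1 minimization with a minimum class-residual
    decision rule). Includes a five-fold cross-validation harness with
    accuracy, sensitivity, precision, Matthews correlation and AUC, a
    synthetic-data generator with a plantable compositional interaction
    signal, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
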