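Package: ppisite
Title: Protein-Protein Interaction Site Prediction with Imbalance-Aware Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interaction interface residues from
    multi-chain structures and per-residue evolutionary conservation features.
    Labels surface and interface residues geometrically (relative solvent
    accessibility and inter-chain carbon distances), encodes each surface
    residue as a spatial-window feature vector over its nearest surface
    neighbours, re-balances the heavily imbalanced interface/non-interface
    classes by repeated edited nearest neighbours (RENN) or instance hardness
    threshold (IHT) undersampling, trains a gradient-boosted tree classifier
    under stratified 10-fold cross-validation, and reports the six standard
    confusion-matrix performance measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
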