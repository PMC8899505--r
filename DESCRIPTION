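Package: chemtk
Title: Cheminformatics and Machine Learning Toolkit for Ligand-Based Drug Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated cheminformatics and QSAR/QSPR modeling toolkit.
    Provides molecular graph processing with MDL SDF V2000 input/output and
    standardization (hydrogen saturation, charge neutralization, aromaticity
    perception), a composable molecular descriptor framework including signed
    2D/3D autocorrelations and druglikeness metrics, maximum common
    substructure similarity with Tanimoto and Tversky indices, a feature
    dataset layer with a self-describing binary format, and trainable models
    (dropout neural networks, decision trees, self-organizing maps with
    applicability-domain scoring, and linear regression) evaluated through
    virtual-screening objective functions under a cross-validation driver.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
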