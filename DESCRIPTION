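Package: chemfeat
Title: Chemogenomic Feature Extraction from Drug-Target Interaction Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies chemogenomic features -- associations between drug
    chemical substructures and protein domains -- from drug-target
    interaction networks. Drug-target pairs are represented by the tensor
    product of a binary compound substructure fingerprint and a binary
    protein domain fingerprint, and sparse (L1) or dense (L2) regularized
    linear classifiers (logistic or hinge loss) are trained to separate
    interacting from non-interacting pairs. Positively weighted pair
    features are extracted as a ranked substructure-domain association
    network. Includes negative sampling, pair-wise and block-wise (cold
    start) cross-validation with ROC/AUC scoring, and a synthetic-data
    generator with planted associations for benchmarking feature recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    glmnet,
    igraph,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
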