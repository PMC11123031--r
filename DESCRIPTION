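Package: pathpair
Title: Metabolite-Pathway Features-Pair Prediction of Metabolic Pathway
    Involvement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a metabolite is involved in a metabolic
    pathway category using a single generic binary classifier trained on
    metabolite-pathway feature pairs. Pathway-level feature vectors are
    built by summing member metabolites' atom-color substructure counts,
    normalizing within bond-inclusion levels, and de-duplicating; pairs
    are formed by a cross join of metabolite and pathway vectors with
    binary involvement labels. Includes an autoencoder for feature
    compression, gradient-boosted-tree and multilayer-perceptron
    backends, Monte-Carlo cross-validation with stratified splits and
    positive oversampling, Matthews-correlation-coefficient evaluation,
    hyperparameter tuning with median pruning, gain-based feature
    importance with softmax aggregation, and a synthetic-data generator
    with planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
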