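Package: moostack
Title: Multiobjective Classifier Selection and Stacked Ensembles for
    Expression Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage framework for automatic classifier selection on
    labeled expression matrices (miRNA/mRNA or binary clinical features).
    Stage one runs an elitist NSGA-II search over a three-part chromosome
    (classifier type, hyperparameters, binary feature mask), scoring each
    candidate by leave-one-out cross-validated macro precision and recall
    while minimizing the number of selected features.  Stage two fuses the
    unique rank-1 Pareto solutions by stacked generalization: base-model
    predictions are appended to the feature matrix and the highest
    F-measure solution's classifier is refit as meta-learner, with
    one-vs-rest decomposition for multiclass problems.  Includes
    chi-squared and signal-to-noise-ratio feature filters, per-sample
    normalization, a stratified train/test splitter, and a synthetic
    expression-data generator with planted informative features.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
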