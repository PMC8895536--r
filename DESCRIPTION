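Package: miescreen
Title: Predicting Molecular Initiating Events from Chemical Perturbation
    Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains and validates binary classifiers that predict molecular
    initiating events (MIEs) from chemical-perturbation gene expression
    profiles. Builds MIE labels from chemical-protein annotation tables with
    literature support levels, merges paralogous targets by Jaccard-based
    hierarchical clustering, assembles balanced active/inactive training sets
    from LINCS-style moderated z-score profiles, fits six classifier families
    with stratified cross-validation and grid search, and assesses
    significance with chemical-replacement empirical null ensembles.
    Validation layers include training-excluded exemplar chemical percentile
    ranks, one-sided Kolmogorov-Smirnov enrichment of moderate-support
    chemicals, and cross-cell-line accuracy comparison anchored to baseline
    target expression. A synthetic-data generator with planted signatures
    makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    class,
    nnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
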