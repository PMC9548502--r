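Package: tcrnodule
Title: TCR Repertoire Diversity Analysis and Classification of Indeterminate Lung Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing peripheral-blood T-cell receptor (TCR)
    CDR3-beta clonotype repertoires in the context of indeterminate lung
    nodule diagnosis. Reads AIRR-style clonotype tables, computes repertoire
    diversity indices (Shannon, Pielou evenness, Gini-Simpson, clonality) and
    clonal-homeostasis bin occupancies, identifies group-exclusive and
    enriched CDR3-beta amino-acid sequences with common-substring motif
    extraction, ranks candidate features by random-forest importance and
    information gain, and fits a support-vector-machine nodule classifier
    whose hyperparameters are tuned by a genetic algorithm, with Youden-cutoff
    diagnostic evaluation and nodule-size/ground-glass stratified reporting.
    A synthetic-cohort generator with heavy-tailed clone-size spectra, public
    clones and a plantable CDR3-beta motif supports end-to-end testing
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    randomForest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
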