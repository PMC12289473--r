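Package: facegestalt
Title: Cohort Similarity Analysis for Ensemble Facial-Phenotype Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying whether a patient cohort shares a facial
    gestalt in a learned embedding space. Images are represented as ensembles
    of unit-norm embedding vectors; similarity is the ensemble-averaged cosine
    distance. The package builds resampled mean-pairwise-distance
    distributions for a test cohort against same-syndrome and random null
    sub-cohorts drawn from a labelled gallery, selects a classification
    threshold by ROC analysis with the Youden index (with k-fold
    cross-validation), performs leave-one-out gallery rank retrieval and
    top-k syndrome match tallies, and ships a hierarchical hypersphere
    simulator of syndrome-structured galleries so every stage is testable
    without access to a real reference database. Cohort phenotype-frequency
    summaries and ACMG-style variant-evidence combining are included for
    clinical table reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
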