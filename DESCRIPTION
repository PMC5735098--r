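Package: seroselect
Title: Resampling-Based Serological Biomarker Discovery for Phage-Antigen Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for discovering disease-specific serological
    biomarkers from two-color phage-displayed antigen microarrays. Spot-level
    Cy5/Cy3 intensities are background-corrected with the normal+exponential
    convolution model, normalized within arrays by loess on the MA scale and
    between arrays by scale (MAD) matching, and summarized to a clones-by-samples
    matrix of log2 ratios. Candidate antigens are then selected by repeated
    random train/test splitting with per-split differential t-tests under
    Benjamini-Hochberg false-discovery-rate control, ranked by their frequency
    of significance, classified with a Gaussian naive Bayes model evaluated by
    ROC analysis on held-out test and validation sets, and correlated with
    clinical covariates via single-clone Spearman and exhaustive five-clone
    aggregate Pearson searches. A synthetic spot-level cohort generator with
    planted differential clones and covariate couplings makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    limma,
    stats,
    tools,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
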