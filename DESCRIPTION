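Package: ieegsift
Title: Semi-Supervised Classification of Intracranial EEG Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised classification of short intracranial EEG (iEEG)
    segments from a small gold-standard label budget. Segments are converted to
    row- and column-normalized log-magnitude spectrograms, embedded by a
    recurrent (GRU) sequence autoencoder with attention trained without labels,
    and classified by per-class kernel density estimates in the embedding space
    (a Naive Bayes style density classifier). Includes a seeded generator of
    synthetic iEEG-like segments in four classes (power-line noise, muscle
    artifact, pathological activity with epileptiform discharges, physiological
    background), the stratified ten-fold label-budget evaluation protocol with
    one-vs-rest AUROC/AUPRC and F1 metrics, a pseudo-prospective rare-discharge
    screening mode, and two-dimensional projections of embeddings for expert
    review.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    signal,
    withr,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
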