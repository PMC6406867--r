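Package: fnirsnet
Title: Functional Brain Network Analysis for fNIRS Synchronized-Tapping Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for graph-theoretical analysis of functional
    near-infrared spectroscopy (fNIRS) hemoglobin time series recorded
    during sensorimotor synchronization (tapping) tasks.  Covers probe-grid
    channel geometry and channel-to-brain-region lookup, band-pass
    filtering with motion-artifact channel rejection, task-block Pearson
    correlation with Fisher z-transformation, proportional thresholding to
    a fixed edge density, degree centrality and top-degree hub detection,
    consensus (prevalence) edges, Ward hierarchical clustering of subjects
    by their degree profiles with a largest-gap dendrogram cut, and
    synchronization-error behavioral statistics.  Includes a synthetic
    multi-subject data generator with planted network hubs, physiological
    noise, motion-artifact steps, and planted synchronization-error
    distributions, so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph
Config/testthat/edition: 3
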