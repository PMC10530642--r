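Package: hfadyn
Title: Dynamics of High-Frequency Activity in Intracranial Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the temporal dynamics of visual category and
    exemplar representations in intracranial EEG. Provides broadband
    high-frequency activity (HFA, 70-150 Hz) envelope estimation from voltage
    traces, epoching with baseline correction and smoothing, selection of
    visually responsive and category-selective electrodes, neural state-space
    trajectory metrics, time-resolved pairwise category decoding with
    shrinkage-regularised linear discriminant analysis and temporal
    generalization, a shared permutation-inference engine (max-statistic and
    cluster-based corrections, FDR), and exemplar-level representational
    similarity analysis with cross-repetition Item and Geometry Reliability
    statistics. A synthetic-data generator with planted transient and
    sustained category codes makes the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
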