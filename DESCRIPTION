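Package: eegreplay
Title: Time-Resolved EEG Decoding of Encoding-Context Reinstatement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains oscillatory-pattern context classifiers on encoding-phase
    EEG and tracks the incidental reinstatement of target and competitor
    contexts during cued memory retrieval. Provides a synthetic multi-subject
    cohort generator with programmable reinstatement events, complex Morlet
    time-frequency decomposition, one-vs-all linear support-vector decoding
    applied bin-by-bin across the retrieval epoch, label-shuffle permutation
    thresholds with Monte-Carlo FDR corroboration, leave-one-subject-out
    window selection with repeated-measures contrasts, and cluster-based
    permutation tests over channel-frequency-time grids.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    igraph,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
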