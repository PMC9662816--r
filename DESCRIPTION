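Package: ccgcolumn
Title: Jitter-Corrected Cross-Correlogram Analysis of Cortical Column Recordings
Version: 0.1.0
Authors@R: person("Columnar", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers functional interactions among simultaneously recorded
    neurons in a single cortical column from trial-structured spike trains.
    Computes firing-rate-normalized cross-correlograms (CCGs), removes
    stimulus locking and slow shared rate fluctuations with an interval-jitter
    correction null, screens CCG peaks for significance, extracts synchrony
    (peak lag) and strength (peak efficacy), classifies CCG shapes into
    synchronous and asynchronous interaction classes by embedding and
    clustering, and quantifies how interactions depend on cortical distance,
    orientation-tuning similarity, and laminar position.  Includes a
    synthetic-column simulator with planted monosynaptic and common-input
    connections for end-to-end validation, and current-source-density tools
    for anchoring laminar depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
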