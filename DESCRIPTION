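Package: rsndyn
Title: Between-Network Neurodynamics Metrics and Small-Sample Classification
    for Resting-State Network Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts static and dynamic connectivity metrics between
    large-scale resting-state brain networks from their activity time
    series: static functional connectivity (Pearson correlation),
    conditional Granger causality with in/out/net causal degrees, Morlet
    wavelet coherence with phase-quadrant time-of-coherence features, and
    emulative powers fitted from an evolutionary-game replicator model on
    networks. Provides permutation-test feature screening, a
    multi-algorithm (SVM, LDA, KNN, decision tree) classification
    benchmark under five validation schemes, a seeded synthetic-cohort
    generator with planted ground-truth effects, and an end-to-end
    pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    e1071,
    rpart,
    class,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
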