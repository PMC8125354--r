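Package: lopocv
Title: Proper and Improper Data Partitioning for Cross-Participant Biosignal Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how dataset partitioning decisions affect
    accuracy estimates of cross-participant biosignal (EEG-style) classifiers.
    Provides a synthetic multi-participant data generator with
    participant-specific covariate shift, entropy and Morlet wavelet band-power
    feature extraction, proper (participant-disjoint) and improper (shuffled)
    cross-validation partition constructors with a leakage auditor,
    inter-participant variability-reducing transformations (shifted Heaviside
    and shift-to-median), covariate-shift diagnostics (histogram KL divergence,
    PCA projections, density-ratio weight grids, t-SNE embedding, neighbour
    purity), and a cross-validation evaluation harness with pooled Wald
    confidence intervals and improper-versus-proper comparison reports.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    glmnet,
    nnet
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
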