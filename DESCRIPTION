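Package: bcidecode
Title: Motor-Imagery EEG Decoding with Online Recursive ICA, Common
    Spatial Patterns, and Adaptive Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decoding pipeline for four-class motor-imagery
    electroencephalography (EEG). Provides a synthetic EEG generator with
    known source mixing, event-related desynchronization and ocular/line
    artifacts; band-pass and notch preprocessing with cue-based epoching;
    online recursive independent component analysis (ORICA) with
    forgetting-factor block updates for streaming artifact removal;
    one-vs-rest multiclass Common Spatial Pattern (CSP) filtering with
    log-variance features; kernel support vector machine and linear
    discriminant classifiers with Platt posterior probabilities and
    confidence-gated unsupervised adaptation; and evaluation by accuracy,
    Cohen's kappa, and the Wolpaw information transfer rate, with a
    comparison harness over feature-extraction and classifier grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    MASS,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
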