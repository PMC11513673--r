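Package: gaitqr
Title: Neurodegenerative Gait Screening from QR-Encoded Stride Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies neurodegenerative gait (amyotrophic lateral
    sclerosis, Huntington's disease, Parkinson's disease, versus healthy
    controls) from per-stride timing features. Each stride record is
    serialized to text, encoded as a QR version-10 symbol at error
    correction level M by a built-in symbology codec (Reed-Solomon over
    GF(256), mask penalty scoring, BCH format and version information),
    rendered as a 100x100 binary image, and classified with a small
    convolutional neural network under stratified k-fold
    cross-validation. Includes a reader for PhysioNet-style gait stride
    tables, a synthetic gait generator with class-specific stride
    statistics for fully offline benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
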