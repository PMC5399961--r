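Package: ar2eeg
Title: Automatic EMG Artifact Reduction for Ictal Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes muscle (EMG) artifact from ictal scalp EEG recordings by
    splitting each record at 16 Hz, decomposing the high band with Infomax
    independent component analysis in 120-second trials, discarding spatially
    focal (myogenic) components, and reconstituting the cleaned high band with
    the untouched low band. Includes EDF (European Data Format) import/export,
    Hilbert-envelope artifact-epoch detection, normalized mutual information
    channel screening, a seeded synthetic ictal-EEG/EMG scene generator with
    exact ground truth, and cleaning-quality scoring against that truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
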