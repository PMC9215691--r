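Package: ictonet
Title: Brain Network Ictogenicity from Interictal EEG Functional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers phase-locking functional networks from resting scalp EEG,
    interrogates them with a stochastic theta-neuron model to quantify brain
    network ictogenicity (BNI) and node ictogenicity (NI), and performs the
    group-level nonparametric comparison used to study photosensitive
    epilepsy cohorts. Includes a synthetic multichannel EEG generator with
    controllable pairwise phase coupling so the full pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    boot,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
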