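Package: pedalbci
Title: Personalized EEG Models for Detecting Pedaling Intent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates personalized brain-computer-interface (BCI)
    models that detect self-initiated pedaling intent from multichannel EEG.
    Provides a documented on-disk session format with a synthetic-session
    generator emulating a cue-paced pedaling protocol with event-related
    desynchronization/synchronization (ERD/ERS) of mu and beta rhythms,
    IMU-based movement-onset detection, per-epoch preprocessing (50 Hz notch,
    Butterworth high-pass, common average reference), five spectral
    feature-extraction algorithms, RBF-kernel support-vector classification in
    offline (leave-one-trial-out cross-validation with majority voting) and
    pseudo-online (sliding-window voting queue) schemes, the weighted
    discriminator (WD) composite metric, and WD-driven procedures that select
    a per-subject best feature algorithm and electrode configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
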