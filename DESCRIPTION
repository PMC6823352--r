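Package: sleepscorer
Title: Automated Sleep Stage Scoring for Mouse EEG/EMG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Scores mouse polysomnography recordings into WAKE, non-REM and REM
    sleep stages from paired EEG/EMG signals. Implements a convolutional
    feature extractor with narrow- and wide-filter branches feeding a
    two-layer bidirectional LSTM scoring head, a two-step (pretraining and
    fine-tuning) optimizer with class-balanced sampling, a certainty-gated
    REM rescoring pass, a hand-crafted-feature random-forest baseline, and
    chance-corrected agreement metrics (per-stage recall and precision,
    accuracy, Cohen's kappa). A synthetic polysomnography generator with
    stage-specific spectral signatures, Markov bout dynamics and configurable
    noise makes the full pipeline testable without animal recordings. Signals
    are read and written as EDF or CSV; hypnograms as TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
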