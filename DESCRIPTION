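Package: tdmnet
Title: Temporal-Difference Minimizing Networks for EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification of multichannel EEG for
    emotion recognition using a temporal-difference minimizing convolutional
    recurrent network. Raw recordings are converted into 4D differential
    entropy tensors (spatial grid x frequency band x time section), encoded
    per section by a convolutional network, and classified by three parallel
    LSTM branches fused with a voting rule. During training a maximum mean
    discrepancy penalty on randomly scrambled within-segment feature groups
    enforces the temporal stability of emotional EEG patterns. Includes a
    synthetic band-limited EEG generator with a controllable within-segment
    drift, cross-validation and ablation harnesses, a segment-length sweep,
    and EDF plus plain-text recording I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    data.table,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    nnet
Config/testthat/edition: 3
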