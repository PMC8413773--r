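Package: semdecode
Title: Decoding Word Semantics from EEG During Symbol Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for decoding word-embedding representations from epoched
    EEG recorded while participants learn an artificial symbol-to-word
    vocabulary through trial and error. Implements the full analysis stack:
    epoch trimming, baseline correction, peak-to-peak and gradient artifact
    rejection, trial selection and averaging, per-dimension ridge regression
    from flattened sensor-by-time features onto word vectors, the 2 vs. 2
    leave-two-out evaluation with cosine distance, permutation significance
    with Benjamini-Hochberg-Yekutieli false-discovery-rate control, and
    bootstrap comparison of accuracies. A synthetic-data module simulates the
    growing-vocabulary reinforcement-learning paradigm (block schedule,
    learner behavior) and generates EEG epochs carrying a planted linear
    semantic signal, so every analysis runs end to end without access to raw
    recordings. Includes sliding-window time-course and electrode-searchlight
    analyses with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
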