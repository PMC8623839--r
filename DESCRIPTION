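Package: emgadapt
Title: Decision-Forest Domain Adaptation for Surface EMG Gesture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying decision-forest transfer learning in myoelectric
    control. Generates synthetic multi-subject, multi-session surface EMG
    recordings with controllable inter-subject pattern divergence and
    inter-session electrode shift, extracts windowed MAV/VAR/mDWT features,
    trains mutable CART random forests, and adapts source forests to a target
    domain by structure expansion/reduction (SER), threshold structure transfer
    (STRUT) and their majority-vote combination (MIX). Includes the
    source/target/test experiment protocols used to compare eight classifier
    variants by balanced accuracy as a function of the number of target
    training repetitions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
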