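Package: rotoregm
Title: Rotational-Activity Detection in Multi-Electrode Atrial Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of rotational activity (rotors) in multi-channel
    endocardial electrograms recorded with a 20-pole star catheter during
    atrial fibrillation. Provides the catheter topology model, a synthetic
    electrogram simulator with ground-truth rotor annotations, the signal
    conditioning pipeline (band-pass and notch filtering, bipolar derivation,
    down-sampling, percentile normalization), a rule-based staircase detector
    of rotational activation operating on unipolar local activation times,
    a window/augmentation/rebalancing dataset builder with patient-wise
    chronological splits, three reference neural classifiers (a dense
    baseline, a convolutional network with recurrent memory cells, and a
    convolutional-recurrent network with gated recurrent units) trained with
    a built-in Adam/backpropagation engine, and confusion-matrix, Matthews
    correlation and ROC/AUC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
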