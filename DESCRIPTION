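Package: micnn
Title: Motor-Imagery EEG Simulation, Time-Frequency Features, CSP, and a
    One-Dimensional Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-class motor-imagery electroencephalography (EEG)
    analysis on the C3/C4 channel pair: simulation of trials with
    event-related desynchronization and synchronization (ERD/ERS) in the mu
    and beta bands, short-time Fourier and continuous Morlet wavelet
    time-frequency features, band-wise common spatial pattern (CSP) filtering
    with log-variance features, and a small one-dimensional convolutional
    neural network trained from scratch by mini-batch gradient descent with
    an exponentially decaying learning rate and inverted dropout. Includes
    stratified splitting, a confusion-matrix and rank-sum AUC metric suite,
    kernel-size sweeps, time-segment analysis, an HDF5 trial container, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    rhdf5,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
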