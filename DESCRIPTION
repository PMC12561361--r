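Package: handbci
Title: Handwriting Trajectory Decoding for Intracortical Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for reconstructing handwriting trajectories from
    intracortical neural recordings and translating them to text.  Implements
    exact and differentiable sequence alignment (dynamic time warping, fastDTW,
    soft-DTW, and the DILATE shape-plus-time distortion loss with analytic
    gradients), synthesis of video-guided handwriting kinematics from stroke
    templates, extraction of standard intracortical features (entire spiking
    activity, spiking-band power, local motor potential, LFP band powers,
    threshold crossings, continuous multiunit activity), Kalman-filter and
    LSTM trajectory decoders with leave-one-character-out cross-validation,
    DTW template-matching character recognition, and the accompanying
    simulation experiments: timeline-resampling misalignment, the
    one-dimensional delayed-copy loss landscape, and multi-day data fusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
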