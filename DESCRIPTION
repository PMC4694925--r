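Package: sornsim
Title: Self-Organizing Recurrent Networks, Spontaneous Activity and
    Sampling-Like Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation of self-organizing recurrent networks
    (SORN) of binary excitatory and inhibitory threshold units shaped by
    spike-timing dependent plasticity, synaptic normalization and intrinsic
    plasticity.  Provides symbolic stimulation protocols (sequence learning,
    two-word priors, ambiguous-cue inference), least-squares linear readouts
    for network decisions and for predicting evoked activity from
    pre-stimulus spontaneous states, spike-train and weight statistics
    (inter-spike intervals, Fano factor curves with mean matching, lognormal
    weight fits, conditional firing probabilities), state-space geometry
    analyses (PCA, nonmetric MDS, nearest-state distances, KL divergence of
    binary pattern distributions, SVD-predicted transition structure), and an
    exact noisy-channel Naive Bayes reference model with grid-search fitting
    to network decision curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
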