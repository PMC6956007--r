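Package: fnspike
Title: Maximum-Likelihood Estimation of FitzHugh-Nagumo Neuron Parameters
    from Spike Timings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the five parameters of a firing-rate-modified
    FitzHugh-Nagumo neuron model to discrete, amplitude-free neural spike
    timings.  The membrane-potential variable drives a logistic-sigmoid
    instantaneous firing rate, spike trains are modelled as an
    inhomogeneous Poisson point process, and parameters are recovered by
    bounded maximum-likelihood optimisation of the point-process
    log-likelihood over repeated stimulus trials.  Includes phased-cosine
    stimulus generation, local-Bernoulli and thinning spike-train
    simulators, a simulation-study driver that tabulates estimator bias
    and dispersion across stimulus designs, segmentation and incremental
    estimation for long recordings, and Kolmogorov-Smirnov interspike-
    interval goodness-of-fit diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
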