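Package: tokentap
Title: Decision and Movement Coregulation Analysis for the Tokens Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for a two-phase sensorimotor
    variant of the Tokens task, in which participants first decide which of
    two growing stimuli will win a frame-wise evidence race and then execute
    a paced finger-tapping sequence. The package generates frame-wise
    evidence sequences and classifies trial difficulty types, simulates
    synthetic participant cohorts with planted condition effects on decision
    threshold, sensorimotor delay and tapping speed, computes behavioral
    endpoint measures (decision duration via simple-reaction-time
    subtraction, objective success probability, tap duration, movement
    accuracy) with robust nonparametric statistics, fits drift-diffusion
    models by maximum likelihood and hierarchical MCMC with
    information-criterion model comparison, and derives response-locked
    psychophysical kernels with slope and peak-latency statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
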