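Package: latentloop
Title: Low-Rank Recurrent Network Models of Decision Dynamics in Coding and
    Residual Subspaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fit low-rank recurrent rate networks to neural population
    activity recorded during delayed-response decision tasks, and decompose
    the fitted dynamics into task-coding and residual subspaces. Provides a
    synthetic-recording generator with the task's epoch structure, linear
    discriminant extraction of sample/choice/response coding axes,
    gradient-based training of the low-rank connectivity on
    condition-averaged or single-trial data, perturbation and choice-flip
    experiments, non-normality diagnostics (Henrici index, pseudospectra,
    ordered Schur decomposition), fixed-point attractor stability analysis,
    single-trial input-bias inference with error-axis estimation, and a
    two-area cortex-thalamus model coupled through low-dimensional
    communication bottlenecks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
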