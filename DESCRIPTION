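Package: perceptbias
Title: Online Bayesian Estimation of Perceptual and Decision Biases in 2AFC Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for disentangling perceptual biases from decision biases in
    two-alternative forced-choice (2AFC) behavioral data with interleaved
    stimulus contexts. Implements a hierarchical Bayesian observer model
    (cumulative-Gaussian psychometric functions with lapse rates, per-context
    perceptual biases and a shared decision bias), online trial-by-trial
    posterior updating by MCMC, and adaptive reward allocation that aligns the
    reward boundary with the running estimate of the perceptual bias so that a
    learning subject has no incentive to compensate for its intrinsic bias.
    Includes a temporal-difference criterion-learning agent for comparing
    reward strategies, a block-randomized synthetic-session generator with
    stationary or drifting biases and optional sequential choice effects, and
    a multi-session linear hypermodel that pools sessions with varying task
    covariates into calibrated per-session priors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
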