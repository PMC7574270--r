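Package: lqtcp
Title: Linear-Quadratic Poisson Tumour Control Probability Modelling from
    Dose-Volume Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Radiobiological outcome modelling for external-beam
    radiotherapy cohorts. Reads differential dose-volume histograms
    (DDVH), converts them to equi-effective dose at 2 Gy per fraction
    (EQD2) and generalized equivalent uniform dose (gEUD, gEUD_2Gy),
    evaluates the linear-quadratic Poisson tumour control probability
    (TCP) model over inhomogeneous dose distributions, and fits its
    parameters (D50, gamma, alpha/beta) to binary biochemical-response
    outcomes by binomial maximum likelihood with simulated annealing and
    profile-likelihood confidence intervals. Companion analyses include
    rank-sum group comparisons of dose metrics, Hosmer-Lemeshow
    calibration testing, a multivariate logistic TCP model with stepwise
    AIC selection, and a synthetic cohort generator that emulates a
    prostate radiotherapy study for validation and power analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
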