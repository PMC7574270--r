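# lqtcp

DVH-based tumour control probability (TCP) modelling for external-beam
radiotherapy cohorts, built around the linear-quadratic Poisson
dose-response model and binomial maximum-likelihood estimation.

The package is aimed at medical physicists and outcome modellers who have
per-patient differential dose-volume histograms (DDVHs) for one or more
target structures (e.g. the prostate gland and an MRI-delineated gross
tumour volume), a binary biochemical-response label per patient, and want
to (a) compare dosimetric indices between responders and non-responders,
(b) fit the dose-response parameters with honest profile-likelihood
uncertainty, and (c) check calibration and covariate effects.

## The model

A total dose `D` at `d` Gy/fraction converts to its 2 Gy-per-fraction
equi-effective dose

    EQD2 = D (1 + d/(α/β)) / (1 + 2/(α/β)),

the homogeneous-dose response is the LQ-Poisson curve

    P(EQD2) = exp(−exp(eγ − (EQD2/D50)(eγ − ln ln 2))),

with `D50` the EQD2 giving 50% control and `γ` the maximum normalized
slope, and an inhomogeneous distribution responds as the volume-weighted
geometric mean over DDVH bins, `TCP = Π P(EQD2_i)^(v_i/V)`. Parameters
`(D50, γ, α/β)` are estimated from binary outcomes `r_j` by minimizing

    −ln L = −Σ_j [ r_j ln P_j + (1 − r_j) ln(1 − P_j) ]

with simulated annealing plus a simplex polish; 95% confidence intervals
come from likelihood profiling (an endpoint that is never bracketed is
reported as *undefined*, which is exactly what happens to α/β under
conventional fractionation). gEUD / gEUD_2Gy dose metrics, Wilcoxon
group comparisons, a Hosmer–Lemeshow calibration test, a stepwise-AIC
multivariate logistic TCP model, and a synthetic cohort generator with
known ground truth round out the toolkit. See the vignette
(`vignettes/tcp-modelling.Rmd`) for the full methods account.

## Worked example

```r
library(lqtcp)

truth <- synthetic_truth(cohort_size = 129, seed = 20201020)
coh <- simulate_cohort(truth)          # DDVHs + Bernoulli responses
coh
#> Cohort 'synthetic (seed 20201020)': 129 patients (17 relapse, 112 relapse-free)
#>   structures: mpmri_gtv, prostate_gland

fit <- fit_tcp(coh, "prostate_gland", free_params = c("d50", "gamma"),
               fixed_values = list(alpha_beta = 1.3))
summary(fit)
#> LQ-Poisson TCP fit: structure 'prostate_gland', 129 patients (17 relapse)
#>   d50          66.073  95% CI [59.29, 68.88]
#>   gamma         5.445  95% CI [2.30, 7.99]
#>   alpha_beta    1.300  fixed
#>   -lnL = 35.5750  (profile CI increment 3.841 on -lnL)
```

The cohort was generated with true `D50 = 66.8` Gy and `γ = 3.81`: at
n = 129 the point estimates land near the truth and both profile CIs cover
it — the wide `γ` interval is what a single 129-patient cohort genuinely
supports. Iso-effect doses invert the fitted curve, with CIs propagated
from the profile-CI extremes:

```r
predict_iso_effect(fit, c(0.90, 0.95))
#>   level  eqd2_gy    lower    upper
#> 1  0.90 74.27958 64.34812 88.47328
#> 2  0.95 77.41540 66.28066 95.96122
```

With the published fitted parameters of the study this package models
(prostate gland: `D50 = 66.8` Gy, `γ = 3.81`, `α/β = 1.3` Gy; GTV:
`D50 = 68.1` Gy, `γ = 4.45`, `α/β = 2.9` Gy) the closed-form inversion
and the model-comparison scan give:

```r
p <- lq_params(66.8, 3.81, 1.3); g <- lq_params(68.1, 4.45, 2.9)
eqd2_for_tcp(c(0.90, 0.95), p)   # 78.5, 83.0 Gy
tcp_deviation_scan(p, g)
#> TCP deviation scan: 601 grid points, 40.0-100.0 Gy
#>   max |dTCP| = 0.1080 at EQD2 = 63.4 Gy
```

A full manifest-or-synthetic pipeline (dose metrics → α/β scan → fit →
iso-effect prediction → calibration → logistic model → JSON/text report)
is available as `run_analysis(analysis_config(...))`, with a thin CLI
wrapper in `inst/scripts/tcp_pipeline.R`.

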