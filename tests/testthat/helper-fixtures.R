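# Fixtures and independent oracles used across the suite.

# Uniform single-bin DDVH at a given dose.
uniform_ddvh <- function(dose, volume = 10, bin_width = 0.1) {
  ddvh(dose, volume, bin_width = bin_width)
}

# Random valid DDVH on a 0.1 Gy grid.
random_ddvh <- function(n_bins = 50, lo = 40, hi = 80) {
  start <- round(runif(1, lo, max(lo + 0.1, hi - n_bins * 0.1)), 1) + 0.05
  ddvh(seq(start, by = 0.1, length.out = n_bins),
       runif(n_bins, 0, 5), bin_width = 0.1)
}

# A small hand-built cohort of uniform-dose patients. `doses` are physical
# total doses; every patient gets `nfx` fractions.
uniform_cohort <- function(doses, resp, nfx = 37, structure = "prostate_gland") {
  cohort(lapply(seq_along(doses), function(i) {
    s <- stats::setNames(list(uniform_ddvh(doses[i])), structure)
    patient_record(sprintf("P%02d", i), nfx, resp[i], s)
  }))
}

# Random small cohort for optimizer-oracle checks: <= max_pat patients,
# <= max_bins DVH bins, responses drawn from a genuine dose-response truth
# (so the ML problem has an interior optimum), mixed responses guaranteed.
random_small_cohort <- function(max_pat = 50, max_bins = 20,
                                truth = lq_params(66.8, 3, 1.3)) {
  n <- sample(10:max_pat, 1)
  repeat {
    pats <- lapply(seq_len(n), function(i) {
      nb <- sample(3:max_bins, 1)
      start <- round(runif(1, 55, 78), 1) + 0.05
      d <- ddvh(seq(start, by = 0.1, length.out = nb), runif(nb, 0.1, 5))
      nfx <- sample(28:42, 1)
      patient_record(sprintf("R%03d", i), nfx,
                     rbinom(1, 1, tcp_ddvh(d, nfx, truth)),
                     list(prostate_gland = d))
    })
    resp <- vapply(pats, `[[`, 0L, "response")
    if (any(resp == 0L) && any(resp == 1L)) return(cohort(pats))
  }
}

# Independent grid-refinement oracle for the 2-parameter (d50, gamma) ML
# problem at fixed alpha/beta: coarse localisation over the full search box,
# then an exhaustive fine grid (0.05 Gy x 0.01) in the located basin.
grid_oracle_nll <- function(coh, structure, alpha_beta) {
  ctx <- lqtcp:::nll_context(coh, structure)
  eval_grid <- function(d50s, gammas) {
    ll <- outer(d50s, gammas, Vectorize(function(d, g)
      lqtcp:::ctx_nll(ctx, d, g, alpha_beta)))
    i <- which(ll == min(ll), arr.ind = TRUE)[1, ]
    list(min = min(ll), d50 = d50s[i[1]], gamma = gammas[i[2]])
  }
  coarse <- eval_grid(seq(2.5, 97.5, by = 2.5), seq(0.1, 9.9, by = 0.2))
  fine <- eval_grid(
    seq(max(0.05, coarse$d50 - 4), min(99.95, coarse$d50 + 4), by = 0.05),
    seq(max(0.01, coarse$gamma - 1), min(9.99, coarse$gamma + 1), by = 0.01))
  fine
}

# Direct high-precision gEUD oracle: plain power-mean summation with the
# doses pre-scaled (sum of terms of comparable magnitude), no log-domain
# tricks shared with the implementation.
geud_direct <- function(centers, volumes, a) {
  w <- volumes / sum(volumes)
  s <- max(centers)
  s * sum(w * (centers / s)^a)^(1 / a)
}

default_arms <- function() {
  list(list(d = 1.8, rx = c(66, 78)),
       list(d = 3.0, rx = c(50, 60)),
       list(d = 7.0, rx = c(26, 32)))
}
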