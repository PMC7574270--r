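test_that("the negative log-likelihood matches analytic and manual cases", {
  # every patient sitting exactly at D50 with a uniform DVH: P_j = 0.5
  p50 <- lq_params(74.05, 3.81, 1.3)           # D50 at the delivered EQD2
  co <- uniform_cohort(rep(74.05, 8), c(1, 1, 0, 1, 0, 1, 1, 1), nfx = 37)
  # 37 fractions of 74.05 Gy: d close to 2 but not exactly; use EQD2-correct D50
  eq <- eqd2(74.05, 74.05 / 37, 1.3)
  expect_equal(negative_log_likelihood(co, "prostate_gland",
                                       lq_params(eq, 3.81, 1.3)),
               8 * log(2))

  # perfect-fit limit: relapse-free patients at saturating dose
  co1 <- uniform_cohort(rep(95.05, 5), rep(1, 5))
  expect_lt(negative_log_likelihood(co1, "prostate_gland",
                                    lq_params(40, 6, 1.3)), 1e-6)

  # 3-patient toy cohort, term-by-term manual summation
  doses <- c(68.05, 74.05, 78.05); resp <- c(0, 1, 1)
  co3 <- uniform_cohort(doses, resp, nfx = 38)
  pars <- lq_params(66.8, 3.81, 1.3)
  Pj <- vapply(doses, function(D)
    poisson_tcp(eqd2(D, D / 38, 1.3), pars), 0)
  manual <- -sum(resp * log(Pj) + (1 - resp) * log(1 - Pj))
  expect_equal(negative_log_likelihood(co3, "prostate_gland", pars), manual)

  # non-negative by construction
  expect_gte(manual, 0)
  # missing structure names the patient
  expect_error(negative_log_likelihood(co3, "gtv", pars), "P01")
})

test_that("fit_tcp is deterministic, optimal and refuses degenerate cohorts", {
  set.seed(21)
  co <- random_small_cohort(40, 15)
  f1 <- fit_tcp(co, "prostate_gland", fixed_values = list(alpha_beta = 1.3),
                seed = 99, compute_ci = FALSE)
  f2 <- fit_tcp(co, "prostate_gland", fixed_values = list(alpha_beta = 1.3),
                seed = 99, compute_ci = FALSE)
  expect_identical(f1$ll_min, f2$ll_min)       # bit-identical under a seed
  expect_identical(coef(f1), coef(f2))

  # optimality spot-check: no random triple beats the fit
  set.seed(22)
  for (i in 1:100) {
    p <- lq_params(runif(1, 5, 95), runif(1, 0.1, 9.5), 1.3)
    expect_gte(negative_log_likelihood(co, "prostate_gland", p) + 1e-9,
               f1$ll_min)
  }

  # grid-refinement oracle agreement on a small cohort
  oracle <- grid_oracle_nll(co, "prostate_gland", 1.3)
  expect_lt(abs(f1$ll_min - oracle$min), 0.01)
  expect_lte(f1$ll_min, oracle$min + 1e-9)     # fit at least as good

  all1 <- uniform_cohort(c(74.05, 76.05), c(1, 1))
  expect_error(fit_tcp(all1, "prostate_gland",
                       fixed_values = list(alpha_beta = 1.3)), "degenerate")
})

test_that("identical patients with mixed responses fit the event rate", {
  co <- uniform_cohort(rep(74.05, 20), rep(c(1, 1, 1, 0), 5), nfx = 37)
  f <- suppressWarnings(
    fit_tcp(co, "prostate_gland", fixed_values = list(alpha_beta = 1.3),
            seed = 5, compute_ci = FALSE))
  expect_equal(unname(f$fitted_tcp[1]), 0.75, tolerance = 1e-3)
  # saturated value: 20 * (0.75 log 0.75 + 0.25 log 0.25) flipped sign
  expect_equal(f$ll_min, -20 * (0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-6)
})

test_that("profile curves and CIs follow the likelihood-profiling rules", {
  set.seed(31)
  tr <- synthetic_truth(cohort_size = 250, seed = 31)
  co <- simulate_cohort(tr)
  f <- fit_tcp(co, "prostate_gland", free_params = c("d50", "gamma"),
               fixed_values = list(alpha_beta = 1.3), seed = 8)
  # profile minimum agrees with the joint minimum
  expect_equal(min(f$profiles$d50$ll_profile), f$ll_min, tolerance = 1e-4)
  # MLE inside every defined CI
  expect_gt(f$params$d50, f$ci_d50$lower)
  expect_lt(f$params$d50, f$ci_d50$upper)
  expect_gt(f$params$gamma, f$ci_gamma$lower)
  expect_lt(f$params$gamma, f$ci_gamma$upper)
  # threshold convention: min + qchisq(0.95, 1) on -lnL
  expect_equal(f$profiles$d50$threshold, f$ll_min + qchisq(0.95, 1),
               tolerance = 1e-4)
  ci <- confint(f)
  expect_equal(unname(ci["d50", ]), c(f$ci_d50$lower, f$ci_d50$upper))

  # monotone curve from its left edge: left endpoint undefined
  cv <- lqtcp:::new_profile_curve("alpha_beta", 1:10, 60 + (1:10) / 2)
  pc <- profile_ci(cv)
  expect_true(pc$undefined[["lower"]])
  expect_false(pc$undefined[["upper"]])
  # threshold arithmetic at the published minima
  cv1 <- lqtcp:::new_profile_curve("alpha_beta", 1:5, 60.02 + c(2, 1, 0, 1, 2))
  expect_equal(profile_ci(cv1)$threshold, 63.86, tolerance = 0.005)
  cv2 <- lqtcp:::new_profile_curve("alpha_beta", 1:5, 61.17 + c(2, 1, 0, 1, 2))
  expect_equal(profile_ci(cv2)$threshold, 65.01, tolerance = 0.005)
  # interpolation: V-shaped curve with known crossing points
  cvv <- lqtcp:::new_profile_curve("x", 0:10, 10 + abs(0:10 - 5))
  pci <- profile_ci(cvv, delta = 2.5)
  expect_equal(pci$lower, 2.5)
  expect_equal(pci$upper, 7.5)
})

test_that("alpha/beta scan argmin is consistent with joint fitting", {
  set.seed(41)
  tr <- synthetic_truth(cohort_size = 150, seed = 41)
  co <- simulate_cohort(tr)
  sc <- alphabeta_scan(co, "prostate_gland", grid = seq(1, 6, by = 0.5),
                       seed = 3)
  # scan curve at each grid point >= the best over the grid, and the argmin
  # value equals a direct 2-parameter refit there
  i <- which(sc$grid == sc$argmin)
  direct <- fit_tcp(co, "prostate_gland",
                    fixed_values = list(alpha_beta = sc$argmin),
                    seed = 3, compute_ci = FALSE)
  expect_equal(sc$ll_profile[i], direct$ll_min, tolerance = 1e-3)
  expect_true(all(diff(sc$grid) > 0))
  expect_error(alphabeta_scan(co, "prostate_gland", grid = numeric()),
               "grid")
})
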