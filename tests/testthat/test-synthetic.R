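test_that("simulated DDVHs respect the construction contract", {
  tr0 <- synthetic_truth(cohort_size = 10, seed = 1,
                         cold_spot = list(prob = 0, depth_shape = 2,
                                          depth_scale = 5, depth_max = 30,
                                          fraction_range = c(0.005, 0.03)))
  set.seed(1)
  for (i in 1:10) {
    d <- simulate_ddvh(74, tr0, "prostate_gland")
    expect_s3_class(d, "ddvh")
    # no cold spot: minimum within 2% of the prescription
    expect_gte(dose_min(d), 74 * 0.98 - 0.1)
    expect_lte(max(d$bin_centers), 74 * 1.02 + 0.1)
  }
  # deterministic under a fixed RNG state
  set.seed(9); a <- simulate_ddvh(76, tr0, "mpmri_gtv")
  set.seed(9); b <- simulate_ddvh(76, tr0, "mpmri_gtv")
  expect_identical(a, b)

  # forced deep tail reaches the low-dose envelope
  tr1 <- synthetic_truth(cohort_size = 10, seed = 1,
                         cold_spot = list(prob = 1, depth_shape = 1e6,
                                          depth_scale = 30 / 1e6,
                                          depth_max = 30,
                                          fraction_range = c(0.01, 0.02)))
  set.seed(2)
  d <- simulate_ddvh(74, tr1, "prostate_gland")
  expect_lt(dose_min(d), 45.5)
  expect_gt(dose_min(d), 42.5)
})

test_that("cohort simulation honours dose/fractionation coupling and seeds", {
  tr <- synthetic_truth(cohort_size = 60, seed = 77)
  co <- simulate_cohort(tr)
  expect_length(co, 60L)
  for (p in co$patients) {
    d <- p$covariates$dose_per_fraction_gy
    expect_gte(d, 1.7); expect_lte(d, 2.7)
    expect_gte(p$n_fractions, 28L); expect_lte(p$n_fractions, 42L)
    rx <- p$covariates$prescription_gy
    expect_gte(rx, 66); expect_lte(rx, 78)
  }
  # regeneration is independent of cohort_size: patient k identical
  tr2 <- synthetic_truth(cohort_size = 5, seed = 77)
  co2 <- simulate_cohort(tr2)
  expect_identical(co2$patients[[3]], co$patients[[3]])
  # full determinism
  expect_identical(simulate_cohort(tr2), co2)
})

test_that("responses are Bernoulli draws from the recorded true TCP", {
  tr <- synthetic_truth(cohort_size = 2000, seed = 55)
  co <- simulate_cohort(tr)
  tt <- attr(co, "true_tcp")
  r <- responses(co)
  # relapse fraction brackets the ~20% failure regime
  expect_gte(mean(r == 0), 0.10)
  expect_lte(mean(r == 0), 0.30)
  # law of large numbers: response rate tracks mean true TCP
  expect_lt(abs(mean(r) - mean(tt)), 0.02)
  # true TCP recomputable from the stored DVHs
  k <- c(1, 500, 1999)
  for (i in k) {
    p <- co$patients[[i]]
    expect_equal(tcp_ddvh(p$structures$prostate_gland, p$n_fractions,
                          tr$tcp_params), tt[i], tolerance = 1e-12)
  }
  # saturation: truth far below delivered doses -> almost no relapse
  tr_hi <- synthetic_truth(tcp_params = lq_params(30, 3.81, 1.3),
                           cohort_size = 200, seed = 56)
  expect_lte(mean(responses(simulate_cohort(tr_hi)) == 0), 0.01)
})

test_that("generated cohorts validate cleanly and refit to the truth", {
  tr <- synthetic_truth(cohort_size = 2000, seed = 13)
  expect_warning(co <- simulate_cohort(tr), NA)   # zero validation warnings
  f <- fit_tcp(co, "prostate_gland", free_params = c("d50", "gamma"),
               fixed_values = list(alpha_beta = 1.3), seed = 2,
               compute_ci = FALSE)
  expect_lt(abs(f$params$d50 - 66.8), 1.0)
  expect_lt(abs(f$params$gamma - 3.81), 0.5)
})

test_that("generator input validation rejects inconsistent settings", {
  expect_error(synthetic_truth(cohort_size = 1), "cohort_size")
  expect_error(synthetic_truth(fraction_range = c(38, 38)), "non-degenerate")
  expect_error(synthetic_truth(response_structure = "bladder"),
               "response_structure")
})
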