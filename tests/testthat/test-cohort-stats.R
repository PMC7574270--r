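test_that("rank-sum group comparison reproduces exact enumeration", {
  # metric returning the patient's uniform dose
  mk <- function(doses, resp) uniform_cohort(doses, resp)
  dm <- function(p, s) dose_min(p$structures[[s]])

  # {1,2,3} vs {4,5,6} scaled into a valid dose range:
  # the extreme arrangement has exact two-sided p = 2 / choose(6,3) = 0.1
  co <- mk(c(61.05, 62.05, 63.05, 64.05, 65.05, 66.05),
           c(0, 0, 0, 1, 1, 1))
  cmpv <- compare_groups(co, dm, "prostate_gland")
  expect_equal(cmpv$p_value, 0.1)
  expect_true(cmpv$exact)
  expect_equal(cmpv$median_relapse, 62.05)
  expect_equal(cmpv$range_control, c(64.05, 66.05))

  # identical value sets in both groups: p = 1 (with ties -> approximation)
  co2 <- mk(rep(c(61.05, 62.05, 63.05), 2), c(0, 0, 0, 1, 1, 1))
  expect_equal(compare_groups(co2, dm, "prostate_gland")$p_value, 1)

  # invariance under strictly monotone metric transforms
  cmp_log <- compare_groups(co, function(p, s) log(dm(p, s)),
                            "prostate_gland")
  expect_equal(cmp_log$p_value, cmpv$p_value)
  expect_equal(cmp_log$statistic, cmpv$statistic)

  expect_error(compare_groups(mk(c(61.05, 62.05), c(1, 1)), dm,
                              "prostate_gland"), "non-empty")
})

test_that("a dose shift in the relapse group is detected at study size", {
  # BR group systematically ~3 Gy lower minimum dose, n = 26 vs 103
  set.seed(52)
  hits <- 0L
  for (rep in 1:10) {
    d_bc <- round(rnorm(103, 72, 3), 1) + 0.05
    d_br <- round(rnorm(26, 69, 3), 1) + 0.05
    co <- uniform_cohort(c(d_br, d_bc), c(rep(0, 26), rep(1, 103)))
    p <- compare_groups(co, "min_eqd2", "prostate_gland",
                        alpha_beta = 1.3)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 6L)   # majority of replicates significant
})

test_that("Hosmer-Lemeshow groups, statistic and null behaviour are correct", {
  # perfect calibration by design: constant prediction = group event rate
  pred <- rep(0.5, 40)
  obs <- rep(c(0, 1), 20)
  hl <- hosmer_lemeshow(pred, obs, g = 4)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)
  expect_equal(hl$df, 2L)

  # hand-computed 2-group toy, 10 observations
  pred2 <- c(0.1, 0.2, 0.3, 0.4, 0.45, 0.6, 0.7, 0.8, 0.85, 0.9)
  obs2 <- c(0, 0, 1, 0, 1, 1, 0, 1, 1, 1)
  # groups: lowest 5 (E = 1.45, O = 2), highest 5 (E = 3.85, O = 4)
  st <- (2 - 1.45)^2 / (1.45 * (1 - 1.45 / 5)) +
        (4 - 3.85)^2 / (3.85 * (1 - 3.85 / 5))
  hl2 <- hosmer_lemeshow(pred2, obs2, g = 2)
  expect_equal(hl2$statistic, st)
  expect_equal(hl2$p_value, pchisq(st, 0, lower.tail = FALSE))

  # permutation invariance of the statistic
  set.seed(61)
  pred3 <- runif(57, 0.05, 0.95); obs3 <- rbinom(57, 1, pred3)
  h_a <- hosmer_lemeshow(pred3, obs3)
  o <- sample(57)
  h_b <- hosmer_lemeshow(pred3[o], obs3[o])
  expect_equal(h_a$statistic, h_b$statistic)
  # remainder spreading: 57 = 10 groups of sizes 6,6,6,6,6,6,6,5,5,5
  expect_equal(h_a$table$n, c(rep(6, 7), rep(5, 3)))

  expect_error(hosmer_lemeshow(pred3, obs3[-1]), "length")
  expect_error(hosmer_lemeshow(pred3, obs3, g = 1), "g must")
  expect_error(hosmer_lemeshow(c(0.5, 1), c(0, 1), g = 2), "inside")
})

test_that("HL test holds its nominal size under the calibration null", {
  # the chi-squared(g - 2) reference presumes predictions fitted to the
  # same data (the 2 lost df); the null replicate therefore includes the
  # model-fitting step, as in the test's intended use
  set.seed(71)
  rej <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    p0 <- runif(1000, 0.05, 0.95)
    y <- rbinom(1000, 1, p0)
    p <- fitted(glm(y ~ qlogis(p0), family = binomial()))
    rej <- rej + (hosmer_lemeshow(p, y, g = 10)$p_value < 0.05)
  }
  rate <- rej / n_rep
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.10)
})

# cohort whose covariates are controlled exactly: uniform one-bin DVHs make
# gEUD_2Gy equal the EQD2 of the patient's dose, independently per structure
logistic_cohort <- function(n, b, seed) {
  set.seed(seed)
  d_pro <- round(runif(n, 66, 80), 1) + 0.05
  d_gtv <- round(runif(n, 66, 80), 1) + 0.05
  v_pro <- rlnorm(n, log(49), 0.4)
  v_gtv <- rlnorm(n, log(2.3), 0.9)
  gs <- sample(7:9, n, replace = TRUE)
  nfx <- 38L
  x1 <- eqd2(d_pro, d_pro / nfx, 1.3)
  x2 <- eqd2(d_gtv, d_gtv / nfx, 2.9)
  eta <- b[1] + b[2] * x1 + b[3] * x2 + b[4] * v_pro + b[5] * v_gtv + b[6] * gs
  y <- rbinom(n, 1, plogis(eta))
  pats <- lapply(seq_len(n), function(i) patient_record(
    sprintf("L%04d", i), nfx, y[i],
    list(prostate_gland = ddvh(d_pro[i], v_pro[i]),
         mpmri_gtv = ddvh(d_gtv[i], v_gtv[i])),
    gleason_score = gs[i]))
  cohort(pats)
}

test_that("the logistic TCP model recovers coefficients and the null", {
  # null formula value is exactly 0.5
  expect_identical(logistic_tcp_value(rep(0, 6), rep(3, 5)), 0.5)
  expect_identical(logistic_tcp_value(0), 0.5)

  # each true coefficient lands within 2 Wald SEs ~95% of the time; over
  # 5 replicates x 2 signal covariates, allow at most 2 misses
  b_true <- c(-22, 0.35, 0, 0, 0, -0.6)
  inside <- 0L
  for (seed in 81:85) {
    co <- logistic_cohort(1000, b_true, seed = seed)
    full <- fit_logistic_tcp(co, select = FALSE)
    sm <- summary(full$model)$coefficients
    for (nm in c("geud2gy_prostate", "gleason")) {
      bt <- b_true[c(geud2gy_prostate = 2, gleason = 6)[nm]]
      inside <- inside +
        (abs(sm[nm, "Estimate"] - bt) < 2 * sm[nm, "Std. Error"])
    }
  }
  expect_gte(inside, 8L)
  # selection: keeps the true signal, AIC never worse than the full model
  sel <- fit_logistic_tcp(co)
  expect_true("geud2gy_prostate" %in% sel$included)
  expect_lte(sel$aic, sel$aic_full)
})

test_that("stepwise selection drops pure-noise covariates", {
  b_true <- c(-25, 0.38, 0, 0, 0, 0)
  keep_signal <- 0L; extra_noise <- 0L
  for (i in 1:10) {
    co <- logistic_cohort(500, b_true, seed = 900 + i)
    sel <- fit_logistic_tcp(co)
    keep_signal <- keep_signal + ("geud2gy_prostate" %in% sel$included)
    extra_noise <- extra_noise +
      length(setdiff(sel$included, "geud2gy_prostate"))
  }
  expect_gte(keep_signal, 9L)
  # on average well under one spurious covariate per replicate set
  expect_lte(extra_noise, 10L)
})
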