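#' Analysis configuration
#'
#' Settings for the full DVH-to-report pipeline ([run_analysis()]). Exactly
#' one input mode is used: a cohort manifest on disk, or a
#' [synthetic_truth()] specification to simulate from.
#'
#' @param manifest path to a cohort manifest CSV (input mode 1), or `NULL`.
#' @param synthetic a [synthetic_truth()] (input mode 2), or `NULL`.
#' @param structures structure labels to analyse.
#' @param alpha_beta either the string `"scan"` (profile alpha/beta per
#'   structure and use each scan's argmin) or a named numeric vector of
#'   fixed values per structure (e.g. `c(prostate_gland = 1.3,
#'   mpmri_gtv = 2.9)`, or one unnamed value applied to all structures,
#'   e.g. the 1.6 Gy sensitivity setting).
#' @param scan_grid alpha/beta grid used when `alpha_beta = "scan"`.
#' @param volume_effect_a gEUD volume-effect exponent (default -10).
#' @param delta profile-CI increment on `-lnL` (default `qchisq(0.95, 1)`).
#' @param scan_step dose-grid step for the deviation scan in Gy.
#' @param iso_levels TCP levels for iso-effect dose prediction.
#' @param seed RNG seed governing all stochastic stages.
#' @param output_dir directory for report artifacts, or `NULL` to skip
#'   writing.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(manifest = NULL, synthetic = NULL,
                            structures = c("prostate_gland", "mpmri_gtv"),
                            alpha_beta = "scan",
                            scan_grid = seq(0.5, 20, by = 0.5),
                            volume_effect_a = -10,
                            delta = stats::qchisq(0.95, 1),
                            scan_step = 0.1,
                            iso_levels = c(0.90, 0.95),
                            seed = 20201020L,
                            output_dir = NULL) {
  if (is.null(manifest) == is.null(synthetic))
    stop("exactly one input mode: give either manifest or synthetic")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_truth"))
  if (!(scan_step > 0)) stop("scan_step must be positive")
  if (!identical(alpha_beta, "scan")) {
    if (!is.numeric(alpha_beta) || any(alpha_beta <= 0))
      stop("alpha_beta must be \"scan\" or positive value(s)")
    if (length(alpha_beta) == 1L && is.null(names(alpha_beta)))
      alpha_beta <- stats::setNames(rep(alpha_beta, length(structures)),
                                    structures)
    if (!all(structures %in% names(alpha_beta)))
      stop("fixed alpha_beta must cover every analysed structure")
  }
  structure(list(manifest = manifest, synthetic = synthetic,
                 structures = structures, alpha_beta = alpha_beta,
                 scan_grid = scan_grid, volume_effect_a = volume_effect_a,
                 delta = delta, scan_step = scan_step,
                 iso_levels = iso_levels, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Flat key-value YAML mirroring the [analysis_config()] arguments
#' (`manifest`, `structures`, `alpha_beta` — `"scan"` or a mapping —,
#' `volume_effect_a`, `delta`, `scan_step`, `iso_levels`, `seed`,
#' `output_dir`). Synthetic-mode runs are configured in code.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("manifest", "structures", "volume_effect_a", "delta",
               "scan_step", "iso_levels", "seed", "output_dir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$alpha_beta)) {
    ab <- y$alpha_beta
    args$alpha_beta <- if (identical(ab, "scan")) "scan" else unlist(ab)
  }
  if (!is.null(y$scan_grid) && length(y$scan_grid) == 3L &&
      !is.null(names(y$scan_grid)))
    args$scan_grid <- seq(y$scan_grid[["from"]], y$scan_grid[["to"]],
                          by = y$scan_grid[["by"]])
  do.call(analysis_config, args)
}

#' Iso-effect dose prediction with profile-CI propagation
#'
#' Inverts the fitted response curve at each requested TCP level
#' ([eqd2_for_tcp()]); the 95\% CI is obtained by evaluating the inversion
#' at the extremes of the rectangular (D50, gamma) profile-CI region and
#' taking the min/max. At level 0.5 the prediction is the fitted D50 with
#' its own CI.
#'
#' @param fit a [fit_tcp()] result with profile CIs.
#' @param levels TCP levels in (0, 1).
#' @return A data.frame with columns `level, eqd2_gy, lower, upper`
#'   (`NA` bounds where a parameter CI is undefined).
#' @export
predict_iso_effect <- function(fit, levels = c(0.90, 0.95)) {
  stopifnot(inherits(fit, "tcp_fit"))
  est <- eqd2_for_tcp(levels, fit$params)
  ci_d <- fit$ci_d50; ci_g <- fit$ci_gamma
  lo <- hi <- rep(NA_real_, length(levels))
  if (!is.null(ci_d) && !is.null(ci_g) &&
      !any(ci_d$undefined) && !any(ci_g$undefined)) {
    corners <- expand.grid(d50 = c(ci_d$lower, ci_d$upper),
                           gamma = c(ci_g$lower, ci_g$upper))
    vals <- sapply(seq_len(nrow(corners)), function(i)
      eqd2_for_tcp(levels, lq_params(corners$d50[i], corners$gamma[i],
                                     fit$params$alpha_beta)))
    vals <- matrix(vals, nrow = length(levels))
    lo <- apply(vals, 1, min); hi <- apply(vals, 1, max)
  }
  data.frame(level = levels, eqd2_gy = est, lower = lo, upper = hi)
}

#' Run the full TCP analysis pipeline
#'
#' Stages, in order: load or simulate the cohort; per-structure dose-metric
#' group comparisons (minimum physical dose, minimum EQD2, D98\% EQD2,
#' gEUD_2Gy, relapse vs control); per-structure alpha/beta handling (profile
#' scan with argmin selection, or fixed values); LQ-Poisson maximum
#' likelihood fit with profile CIs; iso-effect EQD2 predictions;
#' inter-structure TCP deviation scan (when two structures are analysed);
#' Hosmer-Lemeshow calibration of the fitted TCPs; and the multivariate
#' logistic model (when two structures are analysed). The run is
#' deterministic given the config's seed. When `output_dir` is set,
#' `report.json`, `report.txt` and per-structure scan CSVs are written
#' (plus the simulated DDVH files and manifest in synthetic mode).
#'
#' @param config an [analysis_config()].
#' @param quiet suppress per-stage progress messages?
#' @return A list of class `"analysis_report"`.
#' @export
run_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)   # timing-free, so reports reproduce
    if (!quiet)
      message(sprintf("[%6.1fs] %s", proc.time()[["elapsed"]] - t0, msg))
  }

  # --- stage: input ----------------------------------------------------
  if (!is.null(config$manifest)) {
    say("loading cohort from %s", config$manifest)
    coh <- load_cohort(config$manifest)
  } else {
    truth <- config$synthetic
    truth$seed <- config$seed
    say("simulating cohort (n = %d, seed = %d)", truth$cohort_size,
        config$seed)
    coh <- simulate_cohort(truth)
  }
  r <- responses(coh)
  say("cohort: %d patients, %d relapse", length(coh), sum(r == 0L))

  report <- list(
    provenance = list(seed = config$seed,
                      structures = config$structures,
                      alpha_beta = config$alpha_beta,
                      volume_effect_a = config$volume_effect_a,
                      delta = config$delta,
                      package_version = as.character(utils::packageVersion("lqtcp"))),
    cohort = list(n_patients = length(coh), n_relapse = sum(r == 0L)),
    structures = list()
  )

  two_fits <- list()
  for (s in config$structures) {
    sec <- list()
    # --- stage: alpha/beta ---------------------------------------------
    if (identical(config$alpha_beta, "scan")) {
      say("[%s] alpha/beta profile scan (%d grid points)", s,
          length(config$scan_grid))
      curve <- alphabeta_scan(coh, s, grid = config$scan_grid,
                              seed = config$seed, delta = config$delta)
      ci_ab <- profile_ci(curve, delta = config$delta)
      ab <- curve$argmin
      if (any(ci_ab$undefined))
        say("[%s] WARNING: 95%% CI of alpha/beta undefined within the grid", s)
      sec$alphabeta_scan <- list(
        argmin = ab, ci = c(ci_ab$lower, ci_ab$upper),
        threshold = ci_ab$threshold,
        curve = data.frame(param_value = curve$grid,
                           neg_log_likelihood = curve$ll_profile))
    } else {
      ab <- unname(config$alpha_beta[[s]])
      say("[%s] alpha/beta fixed at %.2f Gy", s, ab)
      sec$alphabeta_fixed <- ab
      curve <- NULL
    }
    # --- stage: group comparisons --------------------------------------
    say("[%s] dose-metric group comparisons", s)
    sec$dose_metrics <- lapply(
      c(dose_min = "dose_min", min_eqd2 = "min_eqd2",
        d98_eqd2 = "d98_eqd2", geud_2gy = "geud_2gy"),
      function(m) {
        cmpv <- compare_groups(coh, m, s, alpha_beta = ab,
                               volume_effect_a = config$volume_effect_a)
        cmpv[c("n_relapse", "median_relapse", "range_relapse",
               "n_control", "median_control", "range_control",
               "statistic", "p_value")]
      })
    # --- stage: TCP fit ------------------------------------------------
    say("[%s] LQ-Poisson ML fit (alpha/beta = %.2f Gy)", s, ab)
    fit <- fit_tcp(coh, s, free_params = c("d50", "gamma"),
                   fixed_values = list(alpha_beta = ab),
                   seed = config$seed, delta = config$delta)
    if (any(fit$optimizer_trace$boundary_flags))
      say("[%s] WARNING: fit converged at a search bound", s)
    two_fits[[s]] <- fit
    iso <- predict_iso_effect(fit, config$iso_levels)
    hl <- hosmer_lemeshow(pmin(pmax(fit$fitted_tcp, 1e-12), 1 - 1e-12), r)
    sec$fit <- list(
      d50 = fit$params$d50, gamma = fit$params$gamma, alpha_beta = ab,
      ll_min = fit$ll_min,
      ci_d50 = c(fit$ci_d50$lower, fit$ci_d50$upper),
      ci_gamma = c(fit$ci_gamma$lower, fit$ci_gamma$upper),
      n_patients = fit$n_patients, n_events = fit$n_events)
    sec$iso_effect <- iso
    sec$hosmer_lemeshow <- list(statistic = hl$statistic, g = hl$groups_g,
                                df = hl$df, p_value = hl$p_value)
    report$structures[[s]] <- sec
  }

  # --- stage: inter-model deviation scan -------------------------------
  if (length(two_fits) == 2L) {
    say("TCP deviation scan between the two fitted models")
    scan <- tcp_deviation_scan(two_fits[[1]]$params, two_fits[[2]]$params,
                               step = config$scan_step)
    report$deviation_scan <- list(
      structures = names(two_fits),
      max_deviation = attr(scan, "max_deviation"),
      at_eqd2 = attr(scan, "at_eqd2"))
    dev_scan_table <- scan
  } else dev_scan_table <- NULL

  # --- stage: logistic model -------------------------------------------
  if (length(config$structures) == 2L) {
    abv <- vapply(config$structures, function(s) {
      sec <- report$structures[[s]]
      if (!is.null(sec$alphabeta_fixed)) sec$alphabeta_fixed
      else sec$alphabeta_scan$argmin
    }, 0)
    say("multivariate logistic TCP model (stepwise AIC)")
    lg <- tryCatch(
      fit_logistic_tcp(coh, structures = config$structures,
                       alpha_beta = abv,
                       volume_effect_a = config$volume_effect_a),
      error = function(e) e)
    if (inherits(lg, "error")) {
      say("WARNING: logistic model failed: %s", conditionMessage(lg))
      report$logistic <- list(error = conditionMessage(lg))
    } else {
      hl_lg <- hosmer_lemeshow(pmin(pmax(predict(lg), 1e-12), 1 - 1e-12), r)
      report$logistic <- list(
        coefficients = as.list(lg$coefficients),
        included = lg$included, aic = lg$aic, aic_full = lg$aic_full,
        p_values = as.list(lg$p_values),
        hosmer_lemeshow = list(statistic = hl_lg$statistic,
                               p_value = hl_lg$p_value))
    }
  }

  report$log <- log_lines
  out <- structure(list(report = report, fits = two_fits,
                        cohort = coh, config = config,
                        deviation_scan = dev_scan_table),
                   class = "analysis_report")

  # --- stage: artifacts ------------------------------------------------
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    say("writing artifacts to %s", config$output_dir)
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report_text(out),
               file.path(config$output_dir, "report.txt"))
    for (s in names(report$structures)) {
      cv <- report$structures[[s]]$alphabeta_scan$curve
      if (!is.null(cv))
        utils::write.csv(cv, file.path(config$output_dir,
                                       sprintf("alphabeta_scan_%s.csv", s)),
                         row.names = FALSE)
    }
    if (!is.null(dev_scan_table))
      utils::write.csv(as.data.frame(dev_scan_table),
                       file.path(config$output_dir, "deviation_scan.csv"),
                       row.names = FALSE)
    if (is.null(config$manifest))
      write_cohort(coh, file.path(config$output_dir, "cohort"))
  }
  out
}

# Human-readable report: doses to 0.1 Gy, probabilities to 3 decimals.
format_report_text <- function(x) {
  rp <- x$report
  L <- c(sprintf("TCP analysis report (seed %d)", rp$provenance$seed),
         sprintf("Cohort: %d patients, %d relapse", rp$cohort$n_patients,
                 rp$cohort$n_relapse), "")
  for (s in names(rp$structures)) {
    sec <- rp$structures[[s]]
    L <- c(L, sprintf("== %s ==", s))
    if (!is.null(sec$alphabeta_scan))
      L <- c(L, sprintf("alpha/beta scan argmin: %.1f Gy (CI %s)",
                        sec$alphabeta_scan$argmin,
                        if (length(sec$alphabeta_scan$ci) < 2L ||
                            anyNA(sec$alphabeta_scan$ci)) "undefined"
                        else sprintf("[%.1f, %.1f]",
                                     sec$alphabeta_scan$ci[1],
                                     sec$alphabeta_scan$ci[2])))
    f <- sec$fit
    fmtci <- function(ci) if (length(ci) < 2L || anyNA(ci)) "undefined"
                          else sprintf("[%.1f, %.1f]", ci[1], ci[2])
    L <- c(L,
      sprintf("D50 = %.1f Gy %s, gamma = %.2f %s, alpha/beta = %.1f Gy",
              f$d50, fmtci(f$ci_d50), f$gamma, fmtci(f$ci_gamma),
              f$alpha_beta),
      sprintf("-lnL = %.2f;  HL: X^2 = %.2f, p = %.3f",
              f$ll_min, sec$hosmer_lemeshow$statistic,
              sec$hosmer_lemeshow$p_value))
    for (i in seq_len(nrow(sec$iso_effect)))
      L <- c(L, sprintf("EQD2 for %.0f%% TCP: %.1f Gy %s",
                        100 * sec$iso_effect$level[i],
                        sec$iso_effect$eqd2_gy[i],
                        fmtci(c(sec$iso_effect$lower[i],
                                sec$iso_effect$upper[i]))))
    for (m in names(sec$dose_metrics)) {
      dm <- sec$dose_metrics[[m]]
      L <- c(L, sprintf(
        "%-10s BR median %.1f (%.1f-%.1f) vs BC %.1f (%.1f-%.1f), p = %.3f",
        m, dm$median_relapse, dm$range_relapse[1], dm$range_relapse[2],
        dm$median_control, dm$range_control[1], dm$range_control[2],
        dm$p_value))
    }
    L <- c(L, "")
  }
  if (!is.null(rp$deviation_scan))
    L <- c(L, sprintf("Max TCP deviation between models: %.3f at %.1f Gy",
                      rp$deviation_scan$max_deviation,
                      rp$deviation_scan$at_eqd2), "")
  if (!is.null(rp$logistic) && is.null(rp$logistic$error)) {
    L <- c(L, "Logistic TCP model (selected covariates):",
           sprintf("  %s", paste(rp$logistic$included, collapse = ", ")),
           sprintf("  AIC %.2f (full %.2f); HL p = %.3f",
                   rp$logistic$aic, rp$logistic$aic_full,
                   rp$logistic$hosmer_lemeshow$p_value))
  }
  L
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(paste(format_report_text(x), collapse = "\n"), "\n")
  invisible(x)
}
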