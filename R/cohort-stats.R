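#' Built-in dose-metric extractors
#'
#' Returns a metric function `(patient_record, structure) -> scalar` by
#' name. Available metrics: `"dose_min"` (minimum physical dose),
#' `"min_eqd2"` (minimum dose as EQD2), `"d98_eqd2"` (near-minimum D98\% as
#' EQD2), `"geud_2gy"` (gEUD of the EQD2-mapped distribution),
#' `"total_volume"`.
#'
#' @param name metric name.
#' @param alpha_beta alpha/beta ratio in Gy for the EQD2-based metrics.
#' @param volume_effect_a gEUD volume-effect exponent (default -10).
#' @return A function of `(patient, structure)`.
#' @export
dose_metric <- function(name = c("dose_min", "min_eqd2", "d98_eqd2",
                                 "geud_2gy", "total_volume"),
                        alpha_beta = NULL, volume_effect_a = -10) {
  name <- match.arg(name)
  if (name %in% c("min_eqd2", "d98_eqd2", "geud_2gy") && is.null(alpha_beta))
    stop("metric '", name, "' needs alpha_beta")
  switch(name,
    dose_min = function(p, s) dose_min(p$structures[[s]]),
    total_volume = function(p, s) total_volume(p$structures[[s]]),
    min_eqd2 = function(p, s)
      dose_min(eqd2_transform(p$structures[[s]], p$n_fractions, alpha_beta)),
    d98_eqd2 = function(p, s)
      dose_at_relative_volume(
        eqd2_transform(p$structures[[s]], p$n_fractions, alpha_beta), 0.98),
    geud_2gy = function(p, s)
      geud_2gy(p$structures[[s]], p$n_fractions, volume_effect_a, alpha_beta)
  )
}

#' Compare a dose metric between relapse and control groups
#'
#' Two-sided Wilcoxon rank-sum comparison of a per-patient dose metric
#' between the biochemical-relapse (response 0) and biochemical-control
#' (response 1) groups: per-group median and min-max range plus the rank-sum
#' p-value. The exact distribution is used when both groups have at most 15
#' patients and no ties; otherwise the normal approximation with continuity
#' correction. Being rank-based, the comparison is invariant under strictly
#' monotone transforms of the metric.
#'
#' @param cohort a [cohort()] with both response groups non-empty.
#' @param metric a metric name accepted by [dose_metric()] or a function
#'   `(patient_record, structure) -> scalar`.
#' @param structure structure label.
#' @param ... passed to [dose_metric()] (e.g. `alpha_beta`).
#' @return A list of class `"group_comparison"`.
#' @export
compare_groups <- function(cohort, metric, structure, ...) {
  stopifnot(inherits(cohort, "cohort"))
  f <- if (is.function(metric)) metric else dose_metric(metric, ...)
  mname <- if (is.function(metric)) "custom" else metric
  vals <- vapply(cohort$patients, f, 0, structure)
  r <- responses(cohort)
  br <- vals[r == 0L]; bc <- vals[r == 1L]
  if (!length(br) || !length(bc))
    stop("both response groups must be non-empty")
  exact <- length(br) <= 15L && length(bc) <= 15L
  wt <- suppressWarnings(
    stats::wilcox.test(br, bc, exact = exact, correct = TRUE))
  structure(list(
    metric = mname, structure = structure,
    n_relapse = length(br), n_control = length(bc),
    median_relapse = stats::median(br), range_relapse = range(br),
    median_control = stats::median(bc), range_control = range(bc),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    exact = exact, values = vals, group = ifelse(r == 1L, "BC", "BR")
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Rank-sum comparison of %s (%s), BR vs BC:\n", x$metric, x$structure))
  cat(sprintf("  BR (n=%d): median %.2f, range %.2f-%.2f\n",
              x$n_relapse, x$median_relapse, x$range_relapse[1], x$range_relapse[2]))
  cat(sprintf("  BC (n=%d): median %.2f, range %.2f-%.2f\n",
              x$n_control, x$median_control, x$range_control[1], x$range_control[2]))
  cat(sprintf("  W = %.1f, two-sided p = %.4f (%s)\n", x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Hosmer-Lemeshow calibration test
#'
#' Sorts observations by predicted probability (stable in input order for
#' ties), partitions them into `g` equal-count risk groups (remainder spread
#' one-per-group to the lowest-risk groups), and forms the Pearson statistic
#' \deqn{X^2 = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g / n_g)}}
#' with `O` observed and `E` expected events per group, referred to a
#' chi-squared distribution with `g - 2` degrees of freedom. A p-value
#' above 0.05 indicates adequate calibration.
#'
#' @param predicted probabilities in (0, 1).
#' @param observed 0/1 outcomes, same length.
#' @param g number of risk groups (default 10).
#' @return A list of class `"hl_test"`: `statistic`, `groups_g`, `df`,
#'   `p_value`, and the per-group table.
#' @export
hosmer_lemeshow <- function(predicted, observed, g = 10L) {
  g <- as.integer(g)
  if (is.na(g) || g < 2L) stop("g must be an integer >= 2")
  n <- length(predicted)
  if (length(observed) != n) stop("predicted and observed lengths differ")
  if (n < g) stop("need at least g observations")
  if (any(predicted <= 0 | predicted >= 1))
    stop("predicted probabilities must lie strictly inside (0, 1)")
  if (!all(observed %in% c(0, 1))) stop("observed must be 0/1")
  o <- order(predicted)            # stable: ties keep input order
  sizes <- rep(n %/% g, g)
  rem <- n %% g
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  grp <- rep.int(seq_len(g), sizes)
  p_s <- predicted[o]; y_s <- observed[o]
  O <- tapply(y_s, grp, sum)
  E <- tapply(p_s, grp, sum)
  ng <- tabulate(grp, g)
  denom <- E * (1 - E / ng)
  stat <- sum((O - E)^2 / denom)
  df <- g - 2L
  structure(list(statistic = stat, groups_g = g, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 table = data.frame(group = seq_len(g), n = ng,
                                    observed = as.vector(O),
                                    expected = as.vector(E))),
            class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow test: X^2 = %.3f on %d df (g = %d), p = %.4f\n",
              x$statistic, x$df, x$groups_g, x$p_value))
  invisible(x)
}

#' Multivariate logistic TCP model with stepwise AIC selection
#'
#' Fits the full logistic control model
#' \deqn{TCP = \frac{1}{1 + e^{-(b_0 + b_1\,gEUD_{2Gy,prostate} + b_2\,gEUD_{2Gy,GTV} + b_3 V_{prostate} + b_4 V_{GTV} + b_5\,Gleason)}}}
#' on the relapse-free indicator by iteratively reweighted least squares
#' ([stats::glm()]), then performs bidirectional stepwise selection
#' minimizing AIC ([MASS::stepAIC()]) starting from the full model, with
#' covariates ordered as listed. With every coefficient zero the model
#' predicts TCP = 0.5 for all patients. gEUD_2Gy covariates are computed
#' per structure with that structure's `alpha_beta`; covariates enter
#' unscaled.
#'
#' @param cohort a [cohort()]; all patients need both structures and (when
#'   `use_gleason`) a Gleason score.
#' @param structures character pair naming the prostate-gland and GTV
#'   structure labels, in that order.
#' @param alpha_beta numeric pair of alpha/beta values (Gy) matching
#'   `structures`.
#' @param volume_effect_a gEUD volume-effect exponent (default -10).
#' @param use_gleason include the Gleason score covariate?
#' @param select perform stepwise AIC selection (otherwise keep the full
#'   model)?
#' @return A list of class `"logistic_tcp"`: `coefficients` (on the printed
#'   TCP scale, i.e. `TCP = plogis(b0 + sum b_i x_i)`), `included`, `aic`,
#'   `p_values` (Wald), the underlying `glm` objects and the model frame.
#' @export
fit_logistic_tcp <- function(cohort,
                             structures = c("prostate_gland", "mpmri_gtv"),
                             alpha_beta = c(1.3, 2.9),
                             volume_effect_a = -10,
                             use_gleason = TRUE, select = TRUE) {
  stopifnot(inherits(cohort, "cohort"), length(structures) == 2L,
            length(alpha_beta) == 2L)
  g1 <- dose_metric("geud_2gy", alpha_beta = alpha_beta[1],
                    volume_effect_a = volume_effect_a)
  g2 <- dose_metric("geud_2gy", alpha_beta = alpha_beta[2],
                    volume_effect_a = volume_effect_a)
  dat <- data.frame(
    control = responses(cohort),
    geud2gy_prostate = vapply(cohort$patients, g1, 0, structures[1]),
    geud2gy_gtv = vapply(cohort$patients, g2, 0, structures[2]),
    volume_prostate = vapply(cohort$patients, function(p)
      total_volume(p$structures[[structures[1]]]), 0),
    volume_gtv = vapply(cohort$patients, function(p)
      total_volume(p$structures[[structures[2]]]), 0),
    row.names = vapply(cohort$patients, `[[`, "", "patient_id"))
  if (use_gleason) {
    gs <- vapply(cohort$patients, `[[`, 1L, "gleason_score")
    if (anyNA(gs)) stop("Gleason score missing for some patients")
    dat$gleason <- as.numeric(gs)
  }
  full <- stats::glm(control ~ ., family = stats::binomial(), data = dat)
  if (!full$converged || any(abs(stats::coef(full)[-1]) > 50))
    stop("separation detected: logistic coefficients diverge")
  final <- if (select)
    MASS::stepAIC(full, direction = "both", trace = 0)
  else full
  sm <- summary(final)
  structure(list(
    coefficients = stats::coef(final),
    included = setdiff(names(stats::coef(final)), "(Intercept)"),
    aic = stats::AIC(final),
    aic_full = stats::AIC(full),
    p_values = sm$coefficients[, "Pr(>|z|)"],
    model = final, full_model = full, data = dat
  ), class = "logistic_tcp")
}

#' @export
print.logistic_tcp <- function(x, ...) {
  cat("Multivariate logistic TCP model (stepwise AIC selection)\n")
  cat("  TCP = plogis(b0 + sum b_i x_i); coefficients:\n")
  for (nm in names(x$coefficients))
    cat(sprintf("    %-18s %10.4f   p = %.4f\n", nm, x$coefficients[nm],
                x$p_values[nm]))
  cat(sprintf("  AIC %.2f (full model %.2f)\n", x$aic, x$aic_full))
  invisible(x)
}

#' Evaluate the logistic TCP formula directly
#'
#' `TCP = 1 / (1 + exp(-(b0 + sum_i b_i x_i)))` in the package's sign
#' convention (positive coefficients increase control probability). Under
#' the null hypothesis that every coefficient is zero the predicted TCP is
#' exactly 0.5 for any covariate vector.
#'
#' @param coefficients numeric vector `(b0, b1, ...)`.
#' @param covariates numeric vector `(x1, ...)`, one shorter than
#'   `coefficients` (the intercept takes no covariate).
#' @return A control probability.
#' @export
logistic_tcp_value <- function(coefficients, covariates = numeric(length(coefficients) - 1L)) {
  if (length(covariates) != length(coefficients) - 1L)
    stop("need one covariate per non-intercept coefficient")
  stats::plogis(coefficients[1L] + sum(coefficients[-1L] * covariates))
}

#' Predicted TCP from the multivariate logistic model
#'
#' @param object a [fit_logistic_tcp()] result.
#' @param newdata optional data.frame of covariates (defaults to the
#'   training frame).
#' @param ... unused.
#' @return Control probabilities.
#' @export
predict.logistic_tcp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    stats::predict(object$model, type = "response")
  else
    stats::predict(object$model, newdata = newdata, type = "response")
}
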