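#' @export
print.tcp_fit <- function(x, ...) {
  cat("LQ-Poisson TCP model fit (binomial maximum likelihood)\n")
  cat(sprintf("  structure: %s   patients: %d (%d relapse)\n",
              x$structure, x$n_patients, x$n_events))
  fx <- function(nm) if (nm %in% x$free_params) "" else " (fixed)"
  cat(sprintf("  D50        = %7.2f Gy%s\n", x$params$d50, fx("d50")))
  cat(sprintf("  gamma      = %7.3f%s\n", x$params$gamma, fx("gamma")))
  cat(sprintf("  alpha/beta = %7.2f Gy%s\n", x$params$alpha_beta, fx("alpha_beta")))
  cat(sprintf("  -lnL = %.4f\n", x$ll_min))
  invisible(x)
}

#' Summarize a fitted LQ-Poisson TCP model
#'
#' @param object a [fit_tcp()] result.
#' @param ... unused.
#' @return A list of class `"summary.tcp_fit"` with the coefficient table
#'   (estimate and 95\% profile CI), the minimized negative log-likelihood
#'   and cohort counts.
#' @export
summary.tcp_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(PARAM_NAMES, function(nm) {
    ci <- object[[paste0("ci_", nm)]]
    data.frame(parameter = nm, estimate = object$params[[nm]],
               lower = if (is.null(ci)) NA_real_ else ci$lower,
               upper = if (is.null(ci)) NA_real_ else ci$upper,
               free = nm %in% object$free_params)
  }))
  structure(list(coefficients = tab, ll_min = object$ll_min,
                 n_patients = object$n_patients, n_events = object$n_events,
                 structure = object$structure, delta = object$delta,
                 trace = object$optimizer_trace),
            class = "summary.tcp_fit")
}

#' @export
print.summary.tcp_fit <- function(x, ...) {
  cat(sprintf("LQ-Poisson TCP fit: structure '%s', %d patients (%d relapse)\n",
              x$structure, x$n_patients, x$n_events))
  tab <- x$coefficients
  for (i in seq_len(nrow(tab))) {
    ci <- if (is.na(tab$lower[i]) && is.na(tab$upper[i])) {
      if (tab$free[i]) "" else "fixed"
    } else {
      sprintf("95%% CI [%s, %s]",
              ifelse(is.na(tab$lower[i]), "undefined", sprintf("%.2f", tab$lower[i])),
              ifelse(is.na(tab$upper[i]), "undefined", sprintf("%.2f", tab$upper[i])))
    }
    cat(sprintf("  %-10s %8.3f  %s\n", tab$parameter[i], tab$estimate[i], ci))
  }
  cat(sprintf("  -lnL = %.4f  (profile CI increment %.3f on -lnL)\n",
              x$ll_min, x$delta))
  invisible(x)
}

#' @export
coef.tcp_fit <- function(object, ...) {
  c(d50 = object$params$d50, gamma = object$params$gamma,
    alpha_beta = object$params$alpha_beta)
}

#' @export
logLik.tcp_fit <- function(object, ...) {
  structure(-object$ll_min, df = length(object$free_params),
            nobs = object$n_patients, class = "logLik")
}

#' @export
confint.tcp_fit <- function(object, parm = NULL, level = 0.95, ...) {
  if (level != 0.95)
    stop("only 95% profile intervals are stored; refit with a custom delta")
  if (is.null(parm)) parm <- PARAM_NAMES
  out <- t(vapply(parm, function(nm) {
    ci <- object[[paste0("ci_", nm)]]
    if (is.null(ci)) c(NA_real_, NA_real_) else c(ci$lower, ci$upper)
  }, numeric(2)))
  colnames(out) <- c("2.5 %", "97.5 %")
  out
}

#' Predict tumour control probabilities from a fitted model
#'
#' @param object a [fit_tcp()] result.
#' @param newdata `NULL` (fitted per-patient TCPs), a numeric vector of
#'   homogeneous EQD2 doses in Gy, or a [cohort()] (per-patient DDVH-based
#'   TCPs for the fitted structure).
#' @param ... unused.
#' @return Numeric vector of control probabilities.
#' @export
predict.tcp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_tcp)
  if (is.numeric(newdata)) return(poisson_tcp(newdata, object$params))
  if (inherits(newdata, "cohort")) {
    ctx <- nll_context(newdata, object$structure)
    return(stats::setNames(ctx_tcp(ctx, object$params), ctx$patient_ids))
  }
  stop("newdata must be NULL, a numeric EQD2 vector, or a cohort")
}

#' @export
fitted.tcp_fit <- function(object, ...) object$fitted_tcp

#' Deviance residuals of a fitted TCP model
#'
#' @param object a [fit_tcp()] result.
#' @param ... unused.
#' @return Signed deviance residuals, one per patient.
#' @export
residuals.tcp_fit <- function(object, ...) {
  p <- pmin(pmax(object$fitted_tcp, 1e-300), 1 - 1e-16)
  r <- object$response
  dev <- -2 * (r * log(p) + (1 - r) * log1p(-p))
  sign(r - p) * sqrt(pmax(dev, 0))
}

#' Simulate binary responses from a fitted TCP model
#'
#' Draws Bernoulli responses for each cohort patient from the fitted
#' per-patient control probabilities (parametric bootstrap of the outcome
#' vector).
#'
#' @param object a [fit_tcp()] result.
#' @param nsim number of replicate response vectors.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param ... unused.
#' @return A data.frame with `nsim` columns of 0/1 responses
#'   (1 = relapse-free), one row per patient.
#' @export
simulate.tcp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$fitted_tcp
  draw <- function() as.data.frame(
    matrix(stats::rbinom(length(p) * nsim, 1L, rep(p, nsim)),
           ncol = nsim, dimnames = list(object$ctx$patient_ids,
                                        paste0("sim_", seq_len(nsim)))))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Plot a fitted LQ-Poisson dose-response curve
#'
#' Draws TCP against homogeneous EQD2 with the 95\% confidence band obtained
#' by propagating the rectangular (D50, gamma) profile-CI extremes, plus
#' tick marks at each patient's equivalent homogeneous EQD2 (the dose whose
#' homogeneous TCP equals the patient's DDVH-based TCP), split by observed
#' response.
#'
#' @param x a [fit_tcp()] result.
#' @param from,to dose range in Gy.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tcp_fit <- function(x, from = 40, to = 100, ...) {
  grid <- seq(from, to, by = 0.2)
  tcp <- poisson_tcp(grid, x$params)
  graphics::plot(grid, tcp, type = "n", ylim = c(0, 1),
                 xlab = "EQD2 (Gy)", ylab = "TCP", ...)
  ci_d <- x$ci_d50; ci_g <- x$ci_gamma
  if (!is.null(ci_d) && !is.null(ci_g) &&
      !any(ci_d$undefined) && !any(ci_g$undefined)) {
    corners <- expand.grid(d50 = c(ci_d$lower, ci_d$upper),
                           gamma = c(ci_g$lower, ci_g$upper))
    band <- sapply(seq_len(nrow(corners)), function(i)
      poisson_tcp(grid, lq_params(corners$d50[i], corners$gamma[i],
                                  x$params$alpha_beta)))
    graphics::polygon(c(grid, rev(grid)),
                      c(apply(band, 1, min), rev(apply(band, 1, max))),
                      col = grDevices::adjustcolor("grey60", 0.4), border = NA)
  }
  graphics::lines(grid, tcp, lwd = 2)
  eq <- eqd2_for_tcp(pmin(pmax(x$fitted_tcp, 1e-12), 1 - 1e-12), x$params)
  graphics::rug(eq[x$response == 1L], side = 3, col = "blue")
  graphics::rug(eq[x$response == 0L], side = 1, col = "red")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
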