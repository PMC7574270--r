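#' Ground-truth settings for synthetic cohort simulation
#'
#' Defines the generative model for a synthetic prostate-radiotherapy
#' cohort: a ground-truth LQ-Poisson dose-response, the prescription-dose
#' and fractionation envelope of a conventionally fractionated IMRT series
#' (66-78 Gy total, 28-42 fractions, 1.7-2.7 Gy per fraction, most plans at
#' 74-76 Gy), log-normal structure volumes matching a typical prostate
#' series (prostate median ~49 cc, GTV median ~2.3 cc), and a cold-spot
#' model producing the occasional low-dose tail that dominates DDVH-based
#' TCP. Responses are Bernoulli draws from each patient's true TCP, giving
#' a relapse fraction around 20\% under the default truth.
#'
#' `fractionation_arms` is a deliberate departure from the emulated study:
#' conventionally fractionated cohorts have nearly constant dose per
#' fraction, which leaves alpha/beta unidentifiable. Supplying arms (each a
#' `list(d = <Gy/fraction>, rx = c(lo, hi))`) generates designed
#' fractionation variability so alpha/beta recovery can be demonstrated.
#'
#' @param tcp_params ground-truth [lq_params()] (default
#'   `lq_params(66.8, 3.81, 1.3)`).
#' @param cohort_size number of patients (default 129).
#' @param prescription_levels named numeric vector: prescription doses (Gy)
#'   with sampling weights.
#' @param fraction_range integer range of fraction numbers.
#' @param dose_per_fraction_range admissible Gy-per-fraction range.
#' @param cold_spot list: `prob` (per-patient probability of a low-dose
#'   tail), `depth_shape`/`depth_scale` (gamma tail depth in Gy),
#'   `depth_max` (truncation, Gy), `fraction_range` (tail volume fraction).
#' @param volume_model named list per structure of `c(meanlog, sdlog)` for
#'   log-normal total volumes in cc.
#' @param structures structure labels to generate.
#' @param response_structure structure whose dose drives the response.
#' @param gleason_weights sampling weights for Gleason scores 7/8/9.
#' @param fractionation_arms `NULL`, or a list of
#'   `list(d = , rx = c(lo, hi))` arms sampled uniformly.
#' @param seed base RNG seed; each patient uses an independent substream
#'   derived from it, so patient `k` is reproducible regardless of
#'   `cohort_size`.
#' @return An object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(
    tcp_params = lq_params(66.8, 3.81, 1.3),
    cohort_size = 129L,
    prescription_levels = c(`66` = 0.05, `70` = 0.05, `72` = 0.10,
                            `74` = 0.35, `76` = 0.35, `78` = 0.10),
    fraction_range = c(28L, 42L),
    dose_per_fraction_range = c(1.7, 2.7),
    cold_spot = list(prob = 0.3, depth_shape = 2, depth_scale = 5,
                     depth_max = 30, fraction_range = c(0.005, 0.03)),
    volume_model = list(
      prostate_gland = c(meanlog = log(49.4), sdlog = 0.40),
      mpmri_gtv = c(meanlog = log(2.3), sdlog = 0.975)),
    structures = c("prostate_gland", "mpmri_gtv"),
    response_structure = "prostate_gland",
    gleason_weights = c(`7` = 0.60, `8` = 0.25, `9` = 0.15),
    fractionation_arms = NULL,
    seed = 20201020L) {
  stopifnot(inherits(tcp_params, "lq_params"))
  cohort_size <- as.integer(cohort_size)
  if (is.na(cohort_size) || cohort_size < 2L)
    stop("cohort_size must be an integer >= 2")
  if (diff(range(as.numeric(names(prescription_levels)))) <= 0)
    stop("prescription levels must span a non-degenerate range")
  if (fraction_range[1] >= fraction_range[2] ||
      dose_per_fraction_range[1] >= dose_per_fraction_range[2])
    stop("fraction and dose-per-fraction ranges must be non-degenerate")
  if (!response_structure %in% structures)
    stop("response_structure must be one of the generated structures")
  for (s in structures)
    if (is.null(volume_model[[s]]) || volume_model[[s]][["sdlog"]] <= 0)
      stop("volume_model must give a positive sdlog for structure ", s)
  structure(list(
    tcp_params = tcp_params, cohort_size = cohort_size,
    prescription_levels = prescription_levels,
    fraction_range = as.integer(fraction_range),
    dose_per_fraction_range = dose_per_fraction_range,
    cold_spot = cold_spot, volume_model = volume_model,
    structures = structures, response_structure = response_structure,
    gleason_weights = gleason_weights,
    fractionation_arms = fractionation_arms, seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic cohort truth: n = %d, D50 = %.1f Gy, gamma = %.2f, alpha/beta = %.1f Gy\n",
              x$cohort_size, x$tcp_params$d50, x$tcp_params$gamma,
              x$tcp_params$alpha_beta))
  cat(sprintf("  prescriptions %s Gy, %d-%d fractions, cold-spot prob %.2f, seed %d\n",
              paste(range(as.numeric(names(x$prescription_levels))), collapse = "-"),
              x$fraction_range[1], x$fraction_range[2],
              x$cold_spot$prob, x$seed))
  invisible(x)
}

# Deterministic per-patient substream seed, independent of cohort_size.
patient_seed <- function(base_seed, k) {
  as.integer(((as.numeric(base_seed) %% 1000003) * 2011 +
                7919 * as.numeric(k)) %% 2147483647)
}

#' Simulate one differential DVH
#'
#' Builds a 0.1 Gy-binned DDVH whose bulk volume is a truncated Gaussian
#' within +/-2\% of the prescription dose, optionally augmented (with the
#' truth's cold-spot probability) by a linearly rising low-dose tail whose
#' depth below the prescription is drawn from a truncated gamma. Total
#' volume is drawn from the structure's log-normal volume model. Uses the
#' current RNG state; seed it (e.g. via the per-patient substreams of
#' [simulate_cohort()]) for reproducibility.
#'
#' @param prescription prescription dose in Gy.
#' @param truth a [synthetic_truth()].
#' @param structure structure label (selects the volume model).
#' @return A [ddvh()].
#' @export
simulate_ddvh <- function(prescription, truth, structure = truth$structures[1]) {
  stopifnot(inherits(truth, "synthetic_truth"))
  w <- 0.1
  vm <- truth$volume_model[[structure]]
  vol_total <- stats::rlnorm(1, vm[["meanlog"]], vm[["sdlog"]])
  # integer bin indices on the global 0.1 Gy grid; center of bin i is (i-1/2)w
  i_bulk <- seq(floor(prescription * 0.98 / w) + 1, floor(prescription * 1.02 / w))
  i_lo <- i_bulk[1]
  cs <- truth$cold_spot
  has_tail <- stats::runif(1) < cs$prob
  depth <- if (has_tail)
    min(stats::rgamma(1, shape = cs$depth_shape, scale = cs$depth_scale),
        cs$depth_max) else 0
  tail_lo <- max(prescription - depth, 0.6)
  i_tail_lo <- floor(tail_lo / w) + 1
  if (has_tail && i_tail_lo < i_bulk[1]) i_lo <- i_tail_lo
  idx <- seq(i_lo, i_bulk[length(i_bulk)])
  centers <- (idx - 0.5) * w
  mu <- prescription * (1 + stats::runif(1, -0.005, 0.005))
  sdev <- prescription * stats::runif(1, 0.004, 0.008)
  dens <- stats::dnorm(centers, mu, sdev)
  dens[centers < prescription * 0.98] <- 0
  dens[dens < max(dens) * 1e-12] <- 0
  dens <- dens / sum(dens)
  if (i_lo < i_bulk[1]) {
    # linear ramp rising toward the bulk
    n_tail <- i_bulk[1] - i_lo
    tail_frac <- stats::runif(1, cs$fraction_range[1], cs$fraction_range[2])
    ramp <- seq_len(n_tail)
    dens <- dens * (1 - tail_frac)
    dens[seq_len(n_tail)] <- ramp / sum(ramp) * tail_frac
  }
  keep <- seq(which(dens > 0)[1], max(which(dens > 0)))
  ddvh(centers[keep], dens[keep] * vol_total, bin_width = w,
       metadata = list(structure = structure, volume_units = "cc"))
}

#' Simulate a synthetic cohort with known per-patient true TCPs
#'
#' For each patient: sample a prescription dose and a fraction number
#' consistent with the admissible dose-per-fraction range (infeasible draws
#' rejected and redrawn), simulate a DDVH per structure, compute the true
#' TCP of the response structure under the ground-truth parameters, and
#' draw the binary response from it. Gleason scores are sampled from the
#' configured categorical distribution. Each patient consumes an
#' independent RNG substream derived from `truth$seed`, so the same patient
#' index always regenerates identically.
#'
#' @param truth a [synthetic_truth()].
#' @return A [cohort()]; `attr(, "true_tcp")` holds the per-patient true
#'   control probabilities, `attr(, "truth")` the generating settings. Each
#'   patient also carries `true_tcp`, `prescription_gy` and
#'   `dose_per_fraction_gy` in its covariates.
#' @export
simulate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- truth$cohort_size
  patients <- vector("list", n)
  true_tcp <- numeric(n)
  rx_levels <- as.numeric(names(truth$prescription_levels))
  for (k in seq_len(n)) {
    patients[[k]] <- with_seed(patient_seed(truth$seed, k), {
      if (is.null(truth$fractionation_arms)) {
        repeat {
          rx <- sample(rx_levels, 1L, prob = truth$prescription_levels)
          nf_lo <- max(truth$fraction_range[1],
                       ceiling(rx / truth$dose_per_fraction_range[2]))
          nf_hi <- min(truth$fraction_range[2],
                       floor(rx / truth$dose_per_fraction_range[1]))
          if (nf_lo <= nf_hi) break
        }
        nfx <- if (nf_lo == nf_hi) nf_lo else sample(nf_lo:nf_hi, 1L)
      } else {
        arm <- truth$fractionation_arms[[
          sample(length(truth$fractionation_arms), 1L)]]
        rx <- stats::runif(1, arm$rx[1], arm$rx[2])
        nfx <- max(1L, round(rx / arm$d))
      }
      structs <- lapply(truth$structures, function(s)
        simulate_ddvh(rx, truth, s))
      names(structs) <- truth$structures
      tt <- tcp_ddvh(structs[[truth$response_structure]], nfx,
                     truth$tcp_params)
      r <- stats::rbinom(1L, 1L, tt)
      gs <- as.integer(sample(names(truth$gleason_weights), 1L,
                              prob = truth$gleason_weights))
      p <- patient_record(sprintf("SYN%04d", k), nfx, r, structs,
                          gleason_score = gs,
                          covariates = list(true_tcp = tt,
                                            prescription_gy = rx,
                                            dose_per_fraction_gy = rx / nfx))
      attr(p, "true_tcp") <- tt
      p
    })
    true_tcp[k] <- attr(patients[[k]], "true_tcp")
  }
  out <- cohort(patients, label = sprintf("synthetic (seed %d)", truth$seed))
  attr(out, "true_tcp") <- true_tcp
  attr(out, "truth") <- truth
  out
}
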