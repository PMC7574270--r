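#' Patient record
#'
#' One patient's dose-volume histograms, fractionation and binary
#' biochemical response. The response follows the relapse-free coding used
#' throughout the package: `1` = relapse-free (biochemical control),
#' `0` = relapse.
#'
#' @param patient_id character scalar, unique within a cohort.
#' @param n_fractions positive integer number of delivered fractions.
#' @param response 0/1 response (1 = relapse-free).
#' @param structures named list of [ddvh()] objects, keyed by structure
#'   label (e.g. `"prostate_gland"`, `"mpmri_gtv"`).
#' @param gleason_score optional integer Gleason score.
#' @param covariates optional named list of scalar covariates.
#' @return An object of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, n_fractions, response, structures,
                           gleason_score = NA_integer_, covariates = list()) {
  patient_id <- as.character(patient_id)
  if (length(patient_id) != 1L || !nzchar(patient_id))
    stop("patient_id must be a non-empty string")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("n_fractions must be a positive integer")
  if (!response %in% c(0, 1))
    stop("response must be 0 (relapse) or 1 (relapse-free), got: ", response)
  if (!is.list(structures) || is.null(names(structures)) ||
      any(!nzchar(names(structures))))
    stop("structures must be a named list of ddvh objects")
  ok <- vapply(structures, inherits, TRUE, what = "ddvh")
  if (!all(ok))
    stop("structure(s) not DDVH objects: ",
         paste(names(structures)[!ok], collapse = ", "))
  structure(
    list(patient_id = patient_id, n_fractions = n_fractions,
         response = as.integer(response), structures = structures,
         gleason_score = gleason_score, covariates = covariates),
    class = "patient_record"
  )
}

#' Patient cohort
#'
#' @param patients list of [patient_record()] objects with unique ids.
#' @param label optional cohort label.
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(patients, label = "") {
  if (!length(patients)) stop("a cohort must contain at least one patient")
  ok <- vapply(patients, inherits, TRUE, what = "patient_record")
  if (!all(ok)) stop("all cohort elements must be patient_record objects")
  ids <- vapply(patients, `[[`, "", "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(patients) <- ids
  structure(list(patients = patients, label = label), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  resp <- vapply(x$patients, `[[`, 0L, "response")
  strs <- sort(unique(unlist(lapply(x$patients, function(p) names(p$structures)))))
  cat(sprintf("Cohort%s: %d patients (%d relapse, %d relapse-free)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$patients), sum(resp == 0L), sum(resp == 1L)))
  cat("  structures:", paste(strs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$patients)

#' Cohort responses
#'
#' @param x a [cohort()].
#' @return Named integer vector of 0/1 responses (1 = relapse-free).
#' @export
responses <- function(x) {
  stopifnot(inherits(x, "cohort"))
  vapply(x$patients, `[[`, 0L, "response")
}

#' Load a cohort from a manifest CSV
#'
#' The manifest has one row per (patient, structure) with columns
#' `patient_id, n_fractions, response, gleason_score, structure, dvh_path`
#' (`gleason_score` may be empty). DVH paths are resolved relative to the
#' manifest's directory unless absolute.
#'
#' @param manifest_path path to the manifest CSV.
#' @param label optional cohort label (defaults to the manifest file name).
#' @return A [cohort()].
#' @export
load_cohort <- function(manifest_path, label = basename(manifest_path)) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("patient_id", "n_fractions", "response", "structure", "dvh_path")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(man) == 0L) stop("manifest is empty; cohorts must be non-empty")
  base <- dirname(manifest_path)
  patients <- lapply(split(man, man$patient_id)[unique(man$patient_id)],
                     function(rows) {
    pid <- rows$patient_id[1L]
    nf <- unique(rows$n_fractions); rv <- unique(rows$response)
    if (length(nf) != 1L || length(rv) != 1L)
      stop("inconsistent n_fractions/response for patient ", pid)
    rvn <- suppressWarnings(as.numeric(rv))
    if (is.na(rvn) || !rvn %in% c(0, 1))
      stop("invalid response '", rv, "' for patient ", pid,
           " (must be 0 or 1)")
    gs <- if ("gleason_score" %in% names(rows)) rows$gleason_score[1L] else ""
    gs <- if (is.na(gs) || !nzchar(gs)) NA_integer_ else as.integer(gs)
    structs <- list()
    for (k in seq_len(nrow(rows))) {
      p <- rows$dvh_path[k]
      full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
      if (!file.exists(full))
        stop("missing DVH file for patient ", pid, ": ", full)
      structs[[rows$structure[k]]] <- read_ddvh(full)
    }
    patient_record(pid, as.integer(nf), rvn, structs, gleason_score = gs)
  })
  cohort(unname(patients), label = label)
}

#' Write a cohort as DDVH files plus a manifest CSV
#'
#' Emits exactly what [load_cohort()] consumes: one DDVH-CSV per
#' (patient, structure) under `dir`, and `manifest.csv` referencing them by
#' relative path.
#'
#' @param x a [cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in x$patients) {
    for (s in names(p$structures)) {
      fn <- sprintf("%s_%s.csv", p$patient_id, gsub("[^A-Za-z0-9_]", "_", s))
      d <- p$structures[[s]]
      d$metadata$patient_id <- p$patient_id
      d$metadata$structure <- s
      write_ddvh(d, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, n_fractions = p$n_fractions,
        response = p$response,
        gleason_score = ifelse(is.na(p$gleason_score), "", p$gleason_score),
        structure = s, dvh_path = fn, stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
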