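#' Differential dose-volume histogram (DDVH)
#'
#' Constructs a validated differential DVH: a table of tissue volume per
#' narrow dose bin for one structure of one patient. Bin doses are bin
#' CENTERS; bin \code{i} covers \code{[center - w/2, center + w/2)} where
#' \code{w} is the bin width (default 0.1 Gy, the usual planning-system
#' export resolution). Physical-dose DDVHs must be on a uniform dose grid;
#' DDVHs mapped to the EQD2 axis (see [eqd2_transform()]) keep their original
#' per-bin volumes on a non-uniform dose grid and are flagged by
#' \code{dose_axis = "EQD2"}.
#'
#' @param bin_centers numeric, strictly increasing bin-center doses in Gy.
#' @param volumes numeric, non-negative absolute volumes per bin in cc
#'   (or percent; see `metadata$volume_units`).
#' @param bin_width bin width in Gy. Ignored (may be `NA`) for EQD2-axis
#'   histograms.
#' @param dose_axis `"physical"` (uniform grid enforced) or `"EQD2"`.
#' @param metadata named list of provenance fields (patient_id, structure,
#'   volume_units, ...).
#' @return An object of class `"ddvh"`.
#' @seealso [read_ddvh()], [total_volume()], [dose_min()],
#'   [dose_at_relative_volume()]
#' @examples
#' d <- ddvh(seq(73.05, 74.95, by = 0.1), rep(2.5, 20))
#' total_volume(d)
#' dose_min(d)
#' @export
ddvh <- function(bin_centers, volumes, bin_width = 0.1,
                 dose_axis = c("physical", "EQD2"), metadata = list()) {
  dose_axis <- match.arg(dose_axis)
  bin_centers <- as.numeric(bin_centers)
  volumes <- as.numeric(volumes)
  if (length(bin_centers) != length(volumes))
    stop("bin_centers and volumes must have equal length")
  if (length(bin_centers) == 0L)
    stop("DDVH must contain at least one bin")
  if (anyNA(bin_centers) || anyNA(volumes))
    stop("DDVH doses and volumes must not contain NA")
  if (any(diff(bin_centers) <= 0))
    stop("bin_centers must be strictly increasing")
  if (any(volumes < 0))
    stop("volumes must be non-negative")
  if (sum(volumes) <= 0)
    stop("total volume must be positive")
  if (any(bin_centers <= 0))
    stop("bin_centers must be positive (prune zero-dose bins first)")
  if (dose_axis == "physical") {
    if (!is.numeric(bin_width) || length(bin_width) != 1L || !(bin_width > 0))
      stop("bin_width must be a positive scalar")
    if (length(bin_centers) > 1L &&
        any(abs(diff(bin_centers) - bin_width) > 1e-9))
      stop("bin spacing is not uniform at the stated bin_width (tolerance 1e-9 Gy)")
  } else {
    bin_width <- NA_real_
  }
  structure(
    list(bin_centers = bin_centers, volumes = volumes,
         bin_width = bin_width, dose_axis = dose_axis, metadata = metadata),
    class = "ddvh"
  )
}

#' @export
print.ddvh <- function(x, ...) {
  cat(sprintf("DDVH (%s dose axis): %d bins, %.3f-%.3f Gy, V = %.2f %s\n",
              x$dose_axis, length(x$bin_centers),
              min(x$bin_centers), max(x$bin_centers),
              sum(x$volumes),
              if (identical(x$metadata$volume_units, "percent")) "%" else "cc"))
  if (!is.null(x$metadata$patient_id) || !is.null(x$metadata$structure))
    cat(sprintf("  patient: %s  structure: %s\n",
                x$metadata$patient_id %||% "?",
                x$metadata$structure %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a DDVH from a plain-text export
#'
#' Parses the DDVH-CSV dialect: UTF-8 text, leading comment lines starting
#' with `#` carrying `key=value` pairs (`patient_id`, `structure`,
#' `bin_width_gy`, `volume_units`, `dose_axis`), a header row
#' `dose_gy,volume`, then one row per bin. Volumes given as percent
#' (`volume_units=percent`) are kept on a 100-unit scale and flagged in the
#' metadata. Zero-dose bins (center at or below half a bin width) are pruned
#' with a warning: a tumour volume inside the treated field never
#' legitimately receives zero dose, and power-mean dose metrics with a
#' negative volume-effect exponent are undefined at zero dose.
#'
#' @param path path to a DDVH-CSV file.
#' @return A [ddvh()] object; metadata records any prune count.
#' @export
read_ddvh <- function(path) {
  if (!file.exists(path)) stop("DDVH file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    m <- regmatches(kv, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", kv))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
    i <- i + 1L
  }
  if (i > length(lines))
    stop("malformed DDVH file (no header row): ", path)
  hdr <- tolower(gsub("\\s", "", lines[i]))
  if (hdr != "dose_gy,volume")
    stop(sprintf("malformed DDVH header at line %d of %s: expected 'dose_gy,volume', got '%s'",
                 i, path, lines[i]))
  body <- lines[-seq_len(i)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("DDVH file has no data rows: ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop(sprintf("malformed DDVH row at line %d of %s", i + bad[1L], path))
  dose <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  vol <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(dose) || anyNA(vol)) {
    j <- which(is.na(dose) | is.na(vol))[1L]
    stop(sprintf("non-numeric DDVH row at line %d of %s", i + j, path))
  }
  w <- as.numeric(meta$bin_width_gy %||% 0.1)
  axis <- meta$dose_axis %||% "physical"
  if (!identical(axis, "EQD2")) {
    if (length(dose) > 1L && any(abs(diff(dose) - w) > 1e-6))
      stop(sprintf("non-uniform bin spacing in %s (expected %.4g Gy steps)", path, w))
  }
  keep <- dose > w / 2 | (identical(axis, "EQD2") & dose > 0)
  pruned <- sum(!keep)
  if (pruned > 0L) {
    warning(sprintf("pruned %d zero-dose bin(s) from %s", pruned, path))
    dose <- dose[keep]; vol <- vol[keep]
  }
  meta$pruned_bins <- pruned
  meta$volume_units <- meta$volume_units %||% "cc"
  if (!is.null(meta$bin_width_gy)) meta$bin_width_gy <- NULL
  ddvh(dose, vol, bin_width = w,
       dose_axis = if (identical(axis, "EQD2")) "EQD2" else "physical",
       metadata = meta)
}

#' Write a DDVH to the plain-text dialect read by [read_ddvh()]
#'
#' Doses and volumes are written with enough digits (\%.9g) for a lossless
#' round-trip at 1e-9.
#'
#' @param x a [ddvh()] object.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_ddvh <- function(x, path) {
  stopifnot(inherits(x, "ddvh"))
  if (sum(x$volumes) <= 0) stop("refusing to write DDVH with zero total volume")
  hdr <- c(
    if (!is.null(x$metadata$patient_id)) sprintf("# patient_id=%s", x$metadata$patient_id),
    if (!is.null(x$metadata$structure)) sprintf("# structure=%s", x$metadata$structure),
    if (!is.na(x$bin_width)) sprintf("# bin_width_gy=%.9g", x$bin_width),
    sprintf("# volume_units=%s", x$metadata$volume_units %||% "cc"),
    if (identical(x$dose_axis, "EQD2")) "# dose_axis=EQD2",
    "dose_gy,volume"
  )
  rows <- sprintf("%.9f,%.9g", x$bin_centers, x$volumes)
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write DDVH to ", path)
  invisible(path)
}

#' Total structure volume of a DDVH
#'
#' @param x a [ddvh()] object.
#' @return Sum of all bin volumes (cc, or percent units if so flagged).
#' @export
total_volume <- function(x) {
  stopifnot(inherits(x, "ddvh"))
  sum(x$volumes)
}

#' Minimum dose with non-zero volume
#'
#' @param x a [ddvh()] object.
#' @return The smallest bin-center dose (Gy) whose bin holds positive volume.
#' @export
dose_min <- function(x) {
  stopifnot(inherits(x, "ddvh"))
  i <- which(x$volumes > 0)
  if (!length(i)) stop("DDVH has no positive-volume bin")
  x$bin_centers[min(i)]
}

# Bin edges of a DDVH: midpoints between centers, extrapolated half-steps at
# the ends. Exact for uniform grids; the natural generalization for
# EQD2-mapped grids.
ddvh_edges <- function(x) {
  d <- x$bin_centers
  if (length(d) == 1L) {
    w <- if (is.na(x$bin_width)) 0.1 else x$bin_width
    return(c(d - w / 2, d + w / 2))
  }
  mid <- (d[-1] + d[-length(d)]) / 2
  c(d[1] - (mid[1] - d[1]), mid, d[length(d)] + (d[length(d)] - mid[length(mid)]))
}

#' Dose covering a given volume fraction (DVH metric D_f)
#'
#' Returns the dose `D` such that at least `fraction` of the total structure
#' volume receives `D` or more (e.g. `fraction = 0.98` is the near-minimum
#' dose D98%). The reverse-cumulative DVH is built by summation from the high
#' dose end and evaluated at bin edges; between-edge values are resolved by
#' linear interpolation, and the result is clamped to the
#' `[dose_min, maximum positive-volume bin center]` range so that
#' `fraction = 1` returns [dose_min()].
#'
#' @param x a [ddvh()] object.
#' @param fraction volume fraction in (0, 1].
#' @return Dose in Gy.
#' @export
dose_at_relative_volume <- function(x, fraction) {
  stopifnot(inherits(x, "ddvh"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be a single value in (0, 1]")
  V <- sum(x$volumes)
  edges <- ddvh_edges(x)
  # cumulative volume receiving >= edge_i: all bins at or above bin i
  cum <- rev(cumsum(rev(x$volumes)))          # at lower edges
  xs <- c(edges[-length(edges)], edges[length(edges)])
  ys <- c(cum, 0)
  target <- fraction * V
  # largest dose D with V(D) >= target; V is non-increasing piecewise linear
  d <- stats::approx(ys, xs, xout = target, ties = max,
                     yleft = xs[length(xs)], yright = xs[1L])$y
  pos <- x$bin_centers[x$volumes > 0]
  min(max(d, pos[1L]), pos[length(pos)])
}
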