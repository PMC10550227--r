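#' Region-of-interest specification
#'
#' @param label Identifier string.
#' @param pixels Logical matrix marking ROI membership, or an n x 2 matrix
#'   of (row, col) indices.
#' @param dims Frame dimensions, required when `pixels` is an index matrix.
#' @return An object of class `roi_spec` holding a logical membership matrix.
#' @export
roi_spec <- function(label, pixels, dims = NULL) {
  if (is.logical(pixels)) {
    m <- pixels
  } else if (is.matrix(pixels) && ncol(pixels) == 2L) {
    if (is.null(dims)) stop("`dims` is required when `pixels` is an index matrix")
    if (any(pixels[, 1] < 1 | pixels[, 1] > dims[1] |
            pixels[, 2] < 1 | pixels[, 2] > dims[2]))
      stop("ROI pixels fall outside the frame bounds")
    m <- matrix(FALSE, dims[1], dims[2]); m[pixels] <- TRUE
  } else stop("`pixels` must be a logical matrix or an n x 2 index matrix")
  if (!any(m)) stop("ROI is empty")
  structure(list(label = label, pixels = m), class = "roi_spec")
}

#' Mean anisotropy over an ROI
#'
#' Arithmetic mean of `r` over the pixels that are both inside the ROI and
#' inside the map's validity mask.
#'
#' @param map An [anisotropy_map()].
#' @param roi An [roi_spec()], or `NULL` to average the whole mask.
#' @return Scalar mean anisotropy.
#' @export
mean_roi <- function(map, roi = NULL) {
  stopifnot(inherits(map, "anisotropy_map"))
  sel <- map$mask
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_spec"))
    if (!identical(dim(roi$pixels), dim(map$r)))
      stop("ROI dimensions do not match the map")
    sel <- sel & roi$pixels
  }
  if (!any(sel)) stop("ROI does not intersect the validity mask")
  mean(map$r[sel])
}

#' Pooled whole-stack anisotropy with a slice-size filter
#'
#' Mean over all valid pixels pooled from the slices whose valid-pixel
#' count is at least `min_pixels` (default 1000), the convention used for
#' whole-islet z-stacks: thin top/bottom slices with few surviving pixels
#' are excluded rather than diluting the pooled mean.
#'
#' @param maps List of [anisotropy_map()] objects (one per z slice).
#' @param min_pixels Minimum `n_valid` for a slice to qualify.
#' @return Scalar pooled mean anisotropy.
#' @export
aggregate_zstack <- function(maps, min_pixels = 1000) {
  stopifnot(length(maps) > 0,
            all(vapply(maps, inherits, logical(1), "anisotropy_map")))
  keep <- vapply(maps, function(m) m$n_valid, numeric(1)) >= min_pixels
  if (!any(keep))
    stop("no slice has at least ", min_pixels, " valid pixels")
  vals <- unlist(lapply(maps[keep], function(m) m$r[m$mask]), use.names = FALSE)
  mean(vals)
}

#' Time-resolved mean-anisotropy trace
#'
#' @param time_s Strictly increasing acquisition times (s).
#' @param r_mean Mean anisotropy per time point.
#' @param n_valid Valid-pixel count per time point.
#' @param phase_bounds Numeric `c(baseline_end, oxidant_end, end)` in
#'   seconds; default `c(300, 600, 1200)` (oxidant on at 5 min, off at
#'   10 min, 20-min assay).
#' @return An object of class `assay_trace`.
#' @export
assay_trace <- function(time_s, r_mean, n_valid = NULL,
                        phase_bounds = c(300, 600, 1200)) {
  if (length(time_s) != length(r_mean))
    stop("time_s and r_mean must have equal length")
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing")
  if (length(phase_bounds) != 3L || any(diff(phase_bounds) <= 0))
    stop("phase_bounds must be three increasing times")
  if (is.null(n_valid)) n_valid <- rep(NA_integer_, length(time_s))
  structure(list(time_s = as.numeric(time_s), r_mean = as.numeric(r_mean),
                 n_valid = n_valid, phase_bounds = as.numeric(phase_bounds)),
            class = "assay_trace")
}

#' @export
print.assay_trace <- function(x, ...) {
  cat(sprintf("<assay_trace> %d points over [%g, %g] s, phases at %s s\n",
              length(x$time_s), min(x$time_s), max(x$time_s),
              paste(x$phase_bounds, collapse = "/")))
  invisible(x)
}

#' @export
plot.assay_trace <- function(x, ylab = "Anisotropy", ...) {
  graphics::plot(x$time_s / 60, x$r_mean, type = "l", xlab = "Time (min)",
                 ylab = ylab, ...)
  graphics::abline(v = x$phase_bounds[1:2] / 60, lty = 2, col = "grey40")
  invisible(x)
}

#' Build an assay trace from per-time-point anisotropy maps
#'
#' Takes the whole-slice mean of each map (all valid pixels) at its
#' acquisition time.
#'
#' @param maps List of [anisotropy_map()] objects, one per time point.
#' @param time_s Strictly increasing times (s), one per map.
#' @param phase_bounds Passed to [assay_trace()].
#' @return An [assay_trace()].
#' @export
build_trace <- function(maps, time_s, phase_bounds = c(300, 600, 1200)) {
  if (length(maps) != length(time_s))
    stop("one time point is required per map")
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing")
  r <- vapply(maps, mean_roi, numeric(1))
  n <- vapply(maps, function(m) m$n_valid, numeric(1))
  assay_trace(time_s, r, n, phase_bounds)
}

#' Re-reference a trace to a baseline time point
#'
#' Shifts the trace so its (interpolated) value at `reference_time_s` is
#' zero, turning absolute anisotropy into a change-in-anisotropy trace.
#' The shift leaves every difference between time points - and hence all
#' assay metrics - unchanged; applying it twice with the same reference is
#' a no-op.
#'
#' @param trace An [assay_trace()].
#' @param reference_time_s Reference time (default 300 s, the end of the
#'   baseline phase).
#' @return The shifted [assay_trace()].
#' @export
delta_trace <- function(trace, reference_time_s = 300) {
  stopifnot(inherits(trace, "assay_trace"))
  if (reference_time_s < min(trace$time_s) || reference_time_s > max(trace$time_s))
    stop("reference time lies outside the trace time span")
  ref <- stats::approx(trace$time_s, trace$r_mean, xout = reference_time_s)$y
  out <- trace
  out$r_mean <- trace$r_mean - ref
  out
}

#' Write a trace as long-format CSV
#'
#' Columns: `time_s`, `r_mean`, `n_valid`.
#'
#' @param trace An [assay_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "assay_trace"))
  utils::write.csv(
    data.frame(time_s = trace$time_s, r_mean = trace$r_mean,
               n_valid = trace$n_valid),
    path, row.names = FALSE)
  invisible(path)
}
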