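#' Per-pixel anisotropy map
#'
#' Result container of [compute_anisotropy()]: the anisotropy raster `r`
#' (NA outside the validity mask), the logical `mask` of pixels that
#' survived preprocessing and the denominator guard, and `n_valid`, the
#' number of `TRUE` mask pixels.
#'
#' @param r Numeric matrix of per-pixel anisotropy, NA where undefined.
#' @param mask Logical matrix of valid pixels.
#' @return An object of class `anisotropy_map`.
#' @export
anisotropy_map <- function(r, mask) {
  if (!identical(dim(r), dim(mask))) stop("`r` and `mask` dimensions differ")
  if (any(is.na(r[mask]))) stop("r must be defined on every mask pixel")
  structure(list(r = r, mask = mask, n_valid = sum(mask)),
            class = "anisotropy_map")
}

#' @export
print.anisotropy_map <- function(x, ...) {
  cat(sprintf("<anisotropy_map> %d x %d px, %d valid (%.1f%%)",
              nrow(x$r), ncol(x$r), x$n_valid,
              100 * x$n_valid / length(x$r)))
  if (x$n_valid > 0)
    cat(sprintf(", mean r = %.4f", mean(x$r[x$mask])))
  cat("\n")
  invisible(x)
}

#' Compute per-pixel steady-state anisotropy
#'
#' Applies the anisotropy formula
#' \deqn{r = \frac{I_\parallel - G I_\perp}{I_\parallel + 2 G I_\perp}}
#' pixel by pixel on masked pixels of a background-subtracted,
#' NA-corrected frame. Pixels whose total intensity (the denominator) is
#' not positive are removed from the mask; `r` is NA outside the mask.
#'
#' @param frame A preprocessed [polarized_frame()].
#' @param optics An [optics_config()] supplying G.
#' @param mask Logical matrix from [threshold_range()]; default keeps all
#'   pixels not flagged during background subtraction.
#' @return An [anisotropy_map()].
#' @export
compute_anisotropy <- function(frame, optics, mask = NULL) {
  stopifnot(inherits(frame, "polarized_frame"), inherits(optics, "optics_config"))
  if (is.null(mask)) {
    mask <- if (is.null(frame$excluded))
      matrix(TRUE, nrow(frame$parallel), ncol(frame$parallel))
    else !frame$excluded
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(frame$parallel)))
    stop("`mask` must be a logical matrix matching the frame")
  g <- optics$g_factor
  denom <- frame$parallel + 2 * g * frame$perpendicular
  mask <- mask & denom > 0
  if (!any(mask)) stop("empty mask after the positive-denominator guard")
  r <- matrix(NA_real_, nrow(frame$parallel), ncol(frame$parallel))
  r[mask] <- (frame$parallel[mask] - g * frame$perpendicular[mask]) / denom[mask]
  anisotropy_map(r, mask)
}

#' Normalize an anisotropy value by the sensor dynamic range
#'
#' Scales a sensor anisotropy by the span between the monomer-locked
#' (upper bound) and constitutive-dimer (lower bound) controls:
#' `r_norm = r_sensor / (r_mono_control - r_dimer_control)`. Useful for
#' comparing responses across imaging conditions that compress the
#' absolute dynamic range (e.g. depth-dependent depolarization).
#'
#' @param r_apollo Sensor anisotropy.
#' @param r_r198p Monomer-locked control anisotropy (upper bound).
#' @param r_tdimer Constitutive-dimer control anisotropy (lower bound).
#' @return `r_apollo / (r_r198p - r_tdimer)`.
#' @export
normalize_anisotropy <- function(r_apollo, r_r198p, r_tdimer) {
  if (!(r_r198p > r_tdimer))
    stop("control failure: monomer-control anisotropy must exceed the ",
         "dimer-control anisotropy (non-positive dynamic range)")
  r_apollo / (r_r198p - r_tdimer)
}

#' Full per-frame preprocessing and anisotropy chain
#'
#' Convenience wrapper running, in order: background subtraction, high-NA
#' correction, total-intensity threshold, and the anisotropy formula.
#' This order (linear corrections before masking and division) is the one
#' used throughout the package.
#'
#' @param frame A raw [polarized_frame()].
#' @param optics An [optics_config()].
#' @param prep A [preprocess_config()].
#' @return An [anisotropy_map()].
#' @export
process_frame <- function(frame, optics, prep) {
  f <- subtract_background(frame, prep)
  f <- apply_na_correction(f, optics)
  mask <- threshold_range(f, prep, g_factor = optics$g_factor)
  compute_anisotropy(f, optics, mask)
}

#' Median-smooth an anisotropy map for display
#'
#' 3x3 median filter intended for figures only; quantification always uses
#' the unfiltered map.
#'
#' @param map An [anisotropy_map()].
#' @return Numeric matrix of smoothed r values (NA outside the mask).
#' @export
smooth_for_display <- function(map) {
  stopifnot(inherits(map, "anisotropy_map"))
  r <- map$r
  n <- nrow(r); m <- ncol(r)
  out <- r
  for (i in seq_len(n)) {
    i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
    for (j in seq_len(m)) {
      if (!map$mask[i, j]) next
      j0 <- max(1L, j - 1L); j1 <- min(m, j + 1L)
      v <- r[i0:i1, j0:j1]
      out[i, j] <- stats::median(v[!is.na(v)])
    }
  }
  out
}
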