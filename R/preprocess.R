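#' Preprocessing configuration
#'
#' Controls background subtraction and the intensity threshold that selects
#' the pixels entering quantification.
#'
#' @param background Background estimate: a scalar applied to both channels,
#'   a length-2 vector `c(parallel, perpendicular)`, or `NULL` to use
#'   `background_region`.
#' @param background_region Optional logical matrix (or n x 2 index matrix)
#'   marking a sensor-free reference region; each channel's background is
#'   the mean of the channel over that region.
#' @param lower_fraction Fraction of the intensity span excluded at the
#'   bottom (default 0.05, i.e. the lower fifth percentile of the range).
#' @param upper_fraction Fraction excluded at the top (default 0.05).
#' @param threshold_mode `"range"` (default): cutoffs at
#'   `min + f * (max - min)` of the total intensity, reading the threshold as
#'   a fraction of the min-max *range*; `"percentile"`: cutoffs at the
#'   `lower_fraction` and `1 - upper_fraction` quantiles of the intensity
#'   distribution.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(background = 0, background_region = NULL,
                              lower_fraction = 0.05, upper_fraction = 0.05,
                              threshold_mode = c("range", "percentile")) {
  threshold_mode <- match.arg(threshold_mode)
  if (lower_fraction < 0 || upper_fraction < 0)
    stop("threshold fractions must be non-negative")
  if (lower_fraction + upper_fraction >= 1)
    stop("lower_fraction + upper_fraction must be < 1")
  if (!is.null(background)) {
    if (!is.numeric(background) || !length(background) %in% 1:2)
      stop("`background` must be a scalar or a length-2 numeric vector")
    if (any(background < 0)) stop("background must be non-negative")
  } else if (is.null(background_region)) {
    stop("either `background` or `background_region` must be given")
  }
  structure(list(background = background,
                 background_region = background_region,
                 lower_fraction = lower_fraction,
                 upper_fraction = upper_fraction,
                 threshold_mode = threshold_mode),
            class = "preprocess_config")
}

region_to_logical <- function(region, dims) {
  if (is.logical(region)) {
    if (!identical(dim(region), dims))
      stop("background_region must match the frame dimensions")
    return(region)
  }
  if (is.matrix(region) && ncol(region) == 2L) {
    if (any(region[, 1] < 1 | region[, 1] > dims[1] |
            region[, 2] < 1 | region[, 2] > dims[2]))
      stop("background_region indices fall outside the frame")
    m <- matrix(FALSE, dims[1], dims[2])
    m[region] <- TRUE
    return(m)
  }
  stop("background_region must be a logical matrix or an n x 2 index matrix")
}

#' Subtract the camera/detector background from both channels
#'
#' Each channel is reduced by its background estimate (a fixed offset or
#' the mean of a reference region). Pixels driven below zero are clamped to
#' zero and flagged in the frame's `excluded` mask so that
#' [threshold_range()] and [compute_anisotropy()] drop them.
#'
#' @param frame A [polarized_frame()].
#' @param cfg A [preprocess_config()].
#' @return The background-subtracted [polarized_frame()].
#' @export
subtract_background <- function(frame, cfg) {
  stopifnot(inherits(frame, "polarized_frame"), inherits(cfg, "preprocess_config"))
  if (!is.null(cfg$background_region)) {
    reg <- region_to_logical(cfg$background_region, dim(frame$parallel))
    if (!any(reg)) stop("background reference region is empty")
    bg <- c(mean(frame$parallel[reg]), mean(frame$perpendicular[reg]))
  } else {
    bg <- rep_len(cfg$background, 2L)
  }
  if (bg[1] >= max(frame$parallel) && bg[2] >= max(frame$perpendicular))
    stop("background exceeds the maximum of both channels everywhere; ",
         "degenerate frame")
  p <- frame$parallel - bg[1]
  q <- frame$perpendicular - bg[2]
  clipped <- p < 0 | q < 0
  p[p < 0] <- 0
  q[q < 0] <- 0
  out <- frame
  out$parallel <- p
  out$perpendicular <- q
  out$excluded <- if (is.null(frame$excluded)) clipped else frame$excluded | clipped
  out
}

#' Total-intensity threshold mask
#'
#' Computes the total (polarization-independent) intensity
#' \eqn{t = I_\parallel + 2 G I_\perp} per pixel and keeps pixels inside the
#' configured band. In `"range"` mode the band is
#' `[t_min + lf * (t_max - t_min), t_max - uf * (t_max - t_min)]`; in
#' `"percentile"` mode it is the `[lf, 1 - uf]` quantile interval. The mask
#' is computed on total intensity, not per channel, so a pixel is kept or
#' dropped in both channels jointly; pixels flagged during background
#' subtraction are excluded.
#'
#' @param frame A background-subtracted [polarized_frame()].
#' @param cfg A [preprocess_config()].
#' @param g_factor G factor used to form the total intensity (default 1).
#' @return Logical matrix: `TRUE` for pixels that survive.
#' @export
threshold_range <- function(frame, cfg, g_factor = 1) {
  stopifnot(inherits(frame, "polarized_frame"), inherits(cfg, "preprocess_config"))
  total <- frame$parallel + 2 * g_factor * frame$perpendicular
  keepable <- if (is.null(frame$excluded)) rep(TRUE, length(total)) else !frame$excluded
  tv <- total[keepable]
  if (!length(tv) || diff(range(tv)) == 0)
    stop("degenerate frame: total intensity has no spread after exclusions")
  if (cfg$threshold_mode == "range") {
    lo <- min(tv) + cfg$lower_fraction * diff(range(tv))
    hi <- max(tv) - cfg$upper_fraction * diff(range(tv))
  } else {
    qs <- stats::quantile(tv, c(cfg$lower_fraction, 1 - cfg$upper_fraction),
                          names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  mask <- total >= lo & total <= hi
  dim(mask) <- dim(frame$parallel)
  if (!is.null(frame$excluded)) mask <- mask & !frame$excluded
  mask
}
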