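#' Paired polarized-emission image frame
#'
#' A `polarized_frame` holds one pair of simultaneously acquired emission
#' images: the component polarized parallel to the excitation polarization
#' (I\eqn{\parallel}) and the perpendicular component (I\eqn{\perp}), as
#' produced by a polarizing beamsplitter in the detection path. It is the
#' atomic input of the anisotropy pipeline.
#'
#' @param parallel Numeric matrix of parallel-channel intensities (counts).
#' @param perpendicular Numeric matrix of perpendicular-channel intensities,
#'   same dimensions as `parallel`.
#' @param depth_um Optional axial position of the frame in micrometres.
#' @param time_s Optional acquisition time in seconds.
#' @param pixel_size_um Lateral pixel size in micrometres (default 1).
#' @param excluded Optional logical matrix flagging pixels to drop from all
#'   downstream masks (e.g. pixels clamped during background subtraction).
#'
#' @return An object of class `polarized_frame`.
#' @export
polarized_frame <- function(parallel, perpendicular,
                            depth_um = NULL, time_s = NULL,
                            pixel_size_um = 1, excluded = NULL) {
  if (!is.matrix(parallel) || !is.matrix(perpendicular))
    stop("`parallel` and `perpendicular` must be matrices")
  if (!identical(dim(parallel), dim(perpendicular)))
    stop("parallel and perpendicular channels must have identical dimensions")
  if (anyNA(parallel) || anyNA(perpendicular))
    stop("intensity channels must not contain NA")
  if (is.null(excluded)) {
    if (any(parallel < 0) || any(perpendicular < 0))
      stop("raw intensities must be non-negative; negatives may only arise ",
           "from explicit background subtraction (which flags them)")
  } else {
    if (!is.logical(excluded) || !identical(dim(excluded), dim(parallel)))
      stop("`excluded` must be a logical matrix matching the channel dimensions")
  }
  structure(
    list(parallel = parallel, perpendicular = perpendicular,
         depth_um = depth_um, time_s = time_s,
         pixel_size_um = pixel_size_um,
         excluded = excluded),
    class = "polarized_frame")
}

#' @export
print.polarized_frame <- function(x, ...) {
  d <- dim(x$parallel)
  cat(sprintf("<polarized_frame> %d x %d px", d[1], d[2]))
  if (!is.null(x$depth_um)) cat(sprintf(", depth %.3g um", x$depth_um))
  if (!is.null(x$time_s)) cat(sprintf(", t = %.4g s", x$time_s))
  cat(sprintf(", pixel %.3g um\n", x$pixel_size_um))
  invisible(x)
}

#' Ordered stack of polarized frames
#'
#' Collects `polarized_frame` objects acquired along one axis: depth
#' (`axis_kind = "z"`, e.g. 1-um steps through an islet) or time
#' (`axis_kind = "time"`, e.g. 10-s intervals through a perfusion assay).
#'
#' @param frames List of [polarized_frame()] objects sharing dimensions and
#'   pixel size.
#' @param axis_kind `"z"` or `"time"`.
#' @param spacing Axis step between consecutive frames (um for z, s for time).
#'   Used to synthesize missing per-frame coordinates as `(index - 1) * spacing`.
#'
#' @return An object of class `polarized_stack`.
#' @export
polarized_stack <- function(frames, axis_kind = c("z", "time"), spacing = 1) {
  axis_kind <- match.arg(axis_kind)
  if (!length(frames)) stop("a polarized_stack needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "polarized_frame")))
    stop("`frames` must all be polarized_frame objects")
  dims <- lapply(frames, function(f) dim(f$parallel))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all frames in a stack must share dimensions")
  px <- vapply(frames, function(f) f$pixel_size_um, numeric(1))
  if (diff(range(px)) > 0)
    stop("all frames in a stack must share pixel_size_um")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a positive scalar")

  field <- if (axis_kind == "z") "depth_um" else "time_s"
  coords <- vapply(seq_along(frames), function(i) {
    v <- frames[[i]][[field]]
    if (is.null(v)) (i - 1) * spacing else v
  }, numeric(1))
  if (length(coords) > 1 && any(diff(coords) <= 0))
    stop("axis coordinates must be strictly increasing")
  for (i in seq_along(frames)) frames[[i]][[field]] <- coords[i]

  structure(list(frames = frames, axis_kind = axis_kind,
                 spacing = spacing, coords = coords),
            class = "polarized_stack")
}

#' @export
print.polarized_stack <- function(x, ...) {
  d <- dim(x$frames[[1]]$parallel)
  cat(sprintf("<polarized_stack> %d frame(s) of %d x %d px, axis %s, spacing %.3g\n",
              length(x$frames), d[1], d[2], x$axis_kind, x$spacing))
  invisible(x)
}

#' @export
length.polarized_stack <- function(x) length(x$frames)

#' G-factor calibration image pair
#'
#' Two frames of a spatially uniform, freely rotating (isotropic) fluorophore
#' solution, one imaged through a half-wave plate and one without. The plate
#' swaps the polarization reaching the two detection paths, so combining both
#' frames cancels detector-path gain bias (see [estimate_g_factor()]).
#'
#' @param with_hwp [polarized_frame()] acquired through the half-wave plate.
#' @param without_hwp [polarized_frame()] acquired without the plate.
#' @return An object of class `calibration_pair`.
#' @export
calibration_pair <- function(with_hwp, without_hwp) {
  if (!inherits(with_hwp, "polarized_frame") ||
      !inherits(without_hwp, "polarized_frame"))
    stop("both calibration images must be polarized_frame objects")
  if (!identical(dim(with_hwp$parallel), dim(without_hwp$parallel)))
    stop("calibration frames must share dimensions")
  structure(list(with_hwp = with_hwp, without_hwp = without_hwp),
            class = "calibration_pair")
}
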