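# Image formation: per pixel, expected total signal S = photons * expression;
# true channel expectations I_par = S (1 + 2 r) / 3 and I_perp = S (1 - r) / 3
# (so that the anisotropy formula at G = 1 returns r exactly); forward
# high-NA mixing; perpendicular-path efficiency 1/G; background offset;
# optional Poisson sampling. Inverting this model is exactly the job of the
# processing chain, which is what the round-trip tests exercise.

render_frame <- function(expression, r_field, imaging, depth_um = NULL,
                         time_s = NULL) {
  s <- imaging$photons_per_pixel * expression
  if (length(r_field) == 1L) r_field <- matrix(r_field, nrow(s), ncol(s))
  p <- s * (1 + 2 * r_field) / 3
  q <- s * (1 - r_field) / 3
  optics <- optics_config(g_factor = 1,
                          numerical_aperture = imaging$numerical_aperture,
                          refractive_index = imaging$refractive_index)
  m <- na_mixing_matrix(optics)
  p_obs <- m[1, 1] * p + m[1, 2] * q
  q_obs <- (m[2, 1] * p + m[2, 2] * q) / imaging$g_factor_true
  p_obs <- p_obs + imaging$background_counts
  q_obs <- q_obs + imaging$background_counts
  if (imaging$poisson_noise) {
    p_obs <- matrix(stats::rpois(length(p_obs), p_obs), nrow(p_obs))
    q_obs <- matrix(stats::rpois(length(q_obs), q_obs), nrow(q_obs))
  }
  polarized_frame(p_obs, q_obs, depth_um = depth_um, time_s = time_s)
}

#' Render a polarized image stack from a phantom and anisotropy field
#'
#' Applies the forward measurement model (see the package vignette) to an
#' expression phantom and a per-frame anisotropy field, producing a
#' [polarized_stack()] with known ground truth.
#'
#' @param phantom A [make_phantom()] result.
#' @param r_field Anisotropy per frame: a scalar or matrix (single frame),
#'   or a list/vector with one scalar or matrix per frame.
#' @param imaging An [imaging_params()]; `imaging$seed`, when set, makes
#'   the Poisson sampling reproducible.
#' @param axis_kind `"z"` or `"time"`.
#' @param coords Axis coordinates (um or s), one per frame; default
#'   `(index - 1) * spacing`.
#' @param spacing Axis spacing used when `coords` is NULL (default 1 um
#'   for z, 10 s for time).
#' @return A [polarized_stack()].
#' @export
render_stack <- function(phantom, r_field, imaging,
                         axis_kind = c("z", "time"), coords = NULL,
                         spacing = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(imaging, "imaging_params"))
  axis_kind <- match.arg(axis_kind)
  if (is.null(spacing)) spacing <- if (axis_kind == "z") 1 else 10
  if (!is.list(r_field) && length(r_field) > 1L && !is.matrix(r_field))
    r_field <- as.list(r_field)
  if (!is.list(r_field)) r_field <- list(r_field)
  n <- length(r_field)
  if (is.null(coords)) coords <- (seq_len(n) - 1) * spacing
  if (length(coords) != n) stop("one coordinate is required per frame")
  with_seed(imaging$seed, {
    frames <- lapply(seq_len(n), function(i) {
      render_frame(phantom$expression, r_field[[i]], imaging,
                   depth_um = if (axis_kind == "z") coords[i] else NULL,
                   time_s = if (axis_kind == "time") coords[i] else NULL)
    })
    polarized_stack(frames, axis_kind = axis_kind, spacing = spacing)
  })
}

#' Simulate a G-factor calibration image pair
#'
#' Renders a spatially uniform isotropic fluorophore solution through the
#' imaging model with and without an ideal half-wave plate (which swaps
#' the polarization entering the two detection paths). A small
#' `sample_anisotropy` can be injected to exercise the bias-cancelling
#' property of the geometric-mean estimator.
#'
#' @param imaging An [imaging_params()].
#' @param shape Image dimensions (default `c(64, 64)`).
#' @param sample_anisotropy Residual anisotropy of the calibration sample
#'   (default 0, ideal isotropic dye).
#' @param seed Optional RNG seed (overrides `imaging$seed`).
#' @return A [calibration_pair()].
#' @export
simulate_calibration_pair <- function(imaging, shape = c(64, 64),
                                      sample_anisotropy = 0, seed = NULL) {
  stopifnot(inherits(imaging, "imaging_params"))
  s <- matrix(imaging$photons_per_pixel, shape[1], shape[2])
  r <- sample_anisotropy
  p_true <- s * (1 + 2 * r) / 3
  q_true <- s * (1 - r) / 3
  optics <- optics_config(1, imaging$numerical_aperture, imaging$refractive_index)
  m <- na_mixing_matrix(optics)
  mk <- function(pt, qt) {
    p <- m[1, 1] * pt + m[1, 2] * qt + imaging$background_counts
    q <- (m[2, 1] * pt + m[2, 2] * qt) / imaging$g_factor_true +
      imaging$background_counts
    if (imaging$poisson_noise) {
      p <- matrix(stats::rpois(length(p), p), nrow(p))
      q <- matrix(stats::rpois(length(q), q), nrow(q))
    }
    polarized_frame(p, q)
  }
  with_seed(seed %||% imaging$seed, {
    without_hwp <- mk(p_true, q_true)
    with_hwp <- mk(q_true, p_true)  # ideal plate swaps the true components
    calibration_pair(with_hwp = with_hwp, without_hwp = without_hwp)
  })
}

#' Simulate a full transient-oxidation assay
#'
#' Chains the kinetic model, the sensor transfer, depth depolarization and
#' the image-formation model into a rendered time series at `dt`-second
#' intervals over the assay, together with its analytic ground truth.
#'
#' @param sensor A [sensor_params()].
#' @param kinetics A [kinetics_params()].
#' @param imaging An [imaging_params()].
#' @param phantom A [make_phantom()] result.
#' @param dt Sampling interval in seconds (default 10).
#' @param depth_um Imaging depth of the time-series slice (default 12 um,
#'   within the first quarter of a typical islet).
#' @param lock `NULL` for the responsive sensor, `"monomer"` or `"dimer"`
#'   to pin the dimer fraction at 0 or 1 (the two control constructs).
#' @param seed Optional RNG seed (overrides `imaging$seed`).
#' @return List with `stack` (rendered [polarized_stack()]),
#'   `truth_trace` (noise-free [assay_trace()] of observed-depth
#'   anisotropy), and `truth_metrics` (list: `diamide_drop`,
#'   `depletion_half_life_s = log(2)/k_ox`,
#'   `recovery_half_life_s = log(2)/k_red`, `baseline_change`).
#' @export
simulate_assay <- function(sensor, kinetics, imaging, phantom,
                           dt = 10, depth_um = 12, lock = NULL, seed = NULL) {
  stopifnot(inherits(sensor, "sensor_params"),
            inherits(kinetics, "kinetics_params"),
            inherits(imaging, "imaging_params"),
            inherits(phantom, "phantom"))
  b <- kinetics$phase_bounds
  times <- seq(0, b[3], by = dt)
  nadph <- simulate_kinetics(kinetics, times)
  pool <- pool_trace(kinetics, times)
  f_d <- if (is.null(lock)) {
    dimer_fraction((1 - nadph) * pool, sensor)
  } else {
    rep(switch(match.arg(lock, c("monomer", "dimer")),
               monomer = 0, dimer = 1), length(times))
  }
  r_true <- ensemble_anisotropy(f_d, sensor)
  r_obs <- apply_depth_scatter(r_true, depth_um, imaging)

  stack <- with_seed(seed %||% imaging$seed,
    render_stack(phantom, as.list(r_obs), imaging, axis_kind = "time",
                 coords = times, spacing = dt))
  truth_trace <- assay_trace(times, r_obs, phase_bounds = b)
  at <- function(tt) r_obs[which.min(abs(times - tt))]
  truth_metrics <- list(
    diamide_drop = at(b[2]) - at(b[1]),
    depletion_half_life_s = if (kinetics$k_ox > 0) log(2) / kinetics$k_ox
                            else NA_real_,
    recovery_half_life_s = if (kinetics$k_red > 0) log(2) / kinetics$k_red
                           else NA_real_,
    baseline_change = at(b[3]) - at(b[1]))
  list(stack = stack, truth_trace = truth_trace, truth_metrics = truth_metrics,
       times = times, r_true = r_true, r_obs = r_obs)
}

#' Simulate a depth (z) series of a sensor state
#'
#' Renders one frame per depth with the depth-depolarization model
#' applied, e.g. to reproduce the control depth profiles: both bounds
#' decline with depth while their separation shrinks by `(1 - alpha)`.
#'
#' @param sensor A [sensor_params()].
#' @param imaging An [imaging_params()].
#' @param phantom A [make_phantom()] result.
#' @param f_d Dimer fraction held fixed across depths (0 for the
#'   monomer-locked control, 1 for the constitutive dimer).
#' @param depths_um Depths in um (default `0:40`, 1-um intervals).
#' @param seed Optional RNG seed.
#' @return List with `stack`, `r_true` (scalar), and `r_obs` per depth.
#' @export
simulate_zstack <- function(sensor, imaging, phantom, f_d,
                            depths_um = 0:40, seed = NULL) {
  r_true <- ensemble_anisotropy(f_d, sensor)
  r_obs <- apply_depth_scatter(rep(r_true, length(depths_um)), depths_um, imaging)
  stack <- with_seed(seed %||% imaging$seed,
    render_stack(phantom, as.list(r_obs), imaging, axis_kind = "z",
                 coords = depths_um,
                 spacing = if (length(depths_um) > 1) diff(depths_um[1:2]) else 1))
  list(stack = stack, r_true = r_true, r_obs = r_obs)
}

#' Process every frame of a stack into anisotropy maps
#'
#' @param stack A [polarized_stack()].
#' @param optics An [optics_config()].
#' @param prep A [preprocess_config()].
#' @return List of [anisotropy_map()] objects, one per frame.
#' @export
process_stack <- function(stack, optics, prep) {
  stopifnot(inherits(stack, "polarized_stack"))
  lapply(stack$frames, process_frame, optics = optics, prep = prep)
}
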