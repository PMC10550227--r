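#' Optical correction state
#'
#' Bundles the two instrument corrections applied before the anisotropy
#' formula: the G factor balancing detection efficiency of the two emission
#' paths, and the aperture factors (`ka`, `kb`, `kc`) describing the
#' polarization mixing introduced by a high-NA objective. The aperture
#' factors are deterministic functions of the numerical aperture and the
#' immersion refractive index and are recomputed here via
#' [compute_na_factors()].
#'
#' @param g_factor Channel-balance factor G > 0 (ratio of parallel to
#'   perpendicular detection efficiency).
#' @param numerical_aperture Objective NA, `0 < NA < refractive_index`.
#' @param refractive_index Immersion-medium refractive index (1.518 for
#'   standard oil).
#' @return An object of class `optics_config` with fields `g_factor`,
#'   `numerical_aperture`, `refractive_index`, `ka`, `kb`, `kc`.
#' @export
optics_config <- function(g_factor = 1, numerical_aperture = 1.3,
                          refractive_index = 1.518) {
  if (!is.numeric(g_factor) || length(g_factor) != 1L || g_factor <= 0)
    stop("`g_factor` must be a positive scalar")
  k <- compute_na_factors(numerical_aperture, refractive_index)
  structure(list(g_factor = g_factor,
                 numerical_aperture = numerical_aperture,
                 refractive_index = refractive_index,
                 ka = k[["ka"]], kb = k[["kb"]], kc = k[["kc"]]),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf("<optics_config> G = %.4g, NA = %.3g / n = %.4g (theta = %.1f deg)\n",
              x$g_factor, x$numerical_aperture, x$refractive_index,
              asin(x$numerical_aperture / x$refractive_index) * 180 / pi))
  cat(sprintf("  ka = %.6g, kb = %.6g, kc = %.6g\n", x$ka, x$kb, x$kc))
  invisible(x)
}

#' High-NA aperture factors
#'
#' A high-NA objective collects emission over a wide cone (half-angle
#' \eqn{\theta = \arcsin(NA/n)}), tilting the polarization basis of
#' off-axis rays so each detected channel mixes in the other true
#' components. Integrating the far-field dipole radiation over the
#' collection cone (solid-angle weight \eqn{\sin\psi}) gives the detected
#' x-polarized intensity of a dipole with squared components
#' \eqn{(\mu_x^2, \mu_y^2, \mu_z^2)} as
#' \eqn{K_b \mu_x^2 + K_c \mu_y^2 + K_a \mu_z^2}, with closed forms
#' (\eqn{c = \cos\theta}):
#' \deqn{K_a = (2 - 3c + c^3)/3,\quad K_b = (5 - 3c - c^2 - c^3)/4,\quad
#'       K_c = (1 - c)^3/12.}
#' In the paraxial limit \eqn{\theta \to 0}, \eqn{K_a/K_b \to 0} and
#' \eqn{K_c/K_b \to 0}, so the induced mixing vanishes.
#'
#' @param numerical_aperture Objective NA.
#' @param refractive_index Immersion refractive index; must exceed NA.
#' @return Named numeric vector `c(ka = , kb = , kc = )`.
#' @export
compute_na_factors <- function(numerical_aperture, refractive_index) {
  na <- numerical_aperture; ri <- refractive_index
  if (!is.numeric(na) || !is.numeric(ri) || length(na) != 1L || length(ri) != 1L)
    stop("NA and refractive index must be scalars")
  if (na <= 0) stop("numerical aperture must be positive")
  if (na >= ri) stop("numerical aperture must be smaller than the refractive index")
  theta <- asin(na / ri)
  # evaluate via d = 1 - cos(theta) = 2 sin^2(theta/2) to avoid the
  # catastrophic cancellation of the raw polynomials at small apertures
  d <- 2 * sin(theta / 2)^2
  cth <- 1 - d
  c(ka = d^2 * (2 + cth) / 3,            # = (2 - 3c + c^3)/3
    kb = d * (cth^2 + 2 * cth + 5) / 4,  # = (5 - 3c - c^2 - c^3)/4
    kc = d^3 / 12)                       # = (1 - c)^3/12
}

#' Forward channel-mixing matrix of a high-NA objective
#'
#' For an excitation-symmetric emitter population the out-of-plane dipole
#' weight equals the in-plane perpendicular weight, so the aperture mixing
#' reduces to a 2x2 linear map on the true channel pair
#' \eqn{(I_\parallel, I_\perp)}:
#' \deqn{I_\parallel^{obs} = I_\parallel + \frac{K_c + K_a}{K_b} I_\perp,
#'   \qquad
#'   I_\perp^{obs} = \frac{K_c}{K_b} I_\parallel +
#'   \frac{K_b + K_a}{K_b} I_\perp,}
#' normalized by \eqn{K_b} so the map is the identity in the paraxial limit.
#'
#' @param optics An [optics_config()].
#' @return A 2x2 matrix mapping `c(parallel, perpendicular)` true
#'   intensities to observed ones.
#' @export
na_mixing_matrix <- function(optics) {
  stopifnot(inherits(optics, "optics_config"))
  with(optics, matrix(c(kb, kc, kc + ka, kb + ka), 2, 2) / kb)
}

#' Invert high-NA polarization mixing
#'
#' Undoes the linear channel mixing of [na_mixing_matrix()] on a detected
#' frame. The objective mixes the *true* polarized components, whereas the
#' detection-path gain imbalance (the G factor) arises downstream of the
#' objective; detected channels are therefore
#' \eqn{(P_{obs}, Q_{obs}) = D \, M \, (P, Q)} with
#' \eqn{D = \mathrm{diag}(1, 1/G)}. This function applies
#' \eqn{D M^{-1} D^{-1}}, returning NA-corrected channels that still carry
#' the gain imbalance - which is exactly what the G term in the anisotropy
#' formula then corrects. The correction is linear and, for any valid
#' `NA < n`, invertible.
#'
#' @param frame A background-subtracted [polarized_frame()].
#' @param optics An [optics_config()]; supplies both the mixing matrix and G.
#' @return The corrected [polarized_frame()].
#' @export
apply_na_correction <- function(frame, optics) {
  stopifnot(inherits(frame, "polarized_frame"), inherits(optics, "optics_config"))
  m <- na_mixing_matrix(optics)
  det_m <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(det_m) || abs(det_m) < 1e-12)
    stop("singular high-NA correction; check NA and refractive index")
  inv <- matrix(c(m[2, 2], -m[2, 1], -m[1, 2], m[1, 1]), 2, 2) / det_m
  g <- optics$g_factor
  p_bal <- frame$parallel
  q_bal <- g * frame$perpendicular       # undo detection gain
  p <- inv[1, 1] * p_bal + inv[1, 2] * q_bal
  q <- inv[2, 1] * p_bal + inv[2, 2] * q_bal
  out <- frame
  out$parallel <- p
  out$perpendicular <- q / g             # restore gain for the r formula
  out
}

#' Forward-mix a frame through the high-NA objective model
#'
#' The exact forward counterpart of [apply_na_correction()]
#' (\eqn{D M D^{-1}}), used by round-trip tests; the simulator's image
#' formation applies the same model with the gain applied explicitly.
#'
#' @inheritParams apply_na_correction
#' @return The mixed [polarized_frame()].
#' @export
apply_na_mixing <- function(frame, optics) {
  stopifnot(inherits(frame, "polarized_frame"), inherits(optics, "optics_config"))
  m <- na_mixing_matrix(optics)
  g <- optics$g_factor
  p_bal <- frame$parallel
  q_bal <- g * frame$perpendicular
  out <- frame
  out$parallel <- m[1, 1] * p_bal + m[1, 2] * q_bal
  out$perpendicular <- (m[2, 1] * p_bal + m[2, 2] * q_bal) / g
  out
}

#' Estimate the G factor from a half-wave-plate calibration pair
#'
#' For an isotropic, fast-rotating fluorophore the true parallel and
#' perpendicular emissions are equal, so any measured channel imbalance is
#' instrumental. Writing the measured without-plate ratio as
#' \eqn{\rho_0 = G s} (with \eqn{s} a residual sample/illumination ratio)
#' and the with-plate ratio, in which the plate swaps the polarization
#' entering the two paths, as \eqn{\rho_1 = G / s}, the geometric mean
#' \eqn{G = \sqrt{\rho_0 \rho_1}} cancels \eqn{s} exactly. A large
#' discrepancy between the two ratios (\eqn{|\rho_0/\rho_1 - 1|} beyond
#' `tol`) indicates a non-ideal plate or a non-isotropic sample and raises
#' a warning.
#'
#' @param cal A [calibration_pair()].
#' @param tol Relative with/without consistency tolerance before warning
#'   (default 0.05).
#' @param background Detector offset subtracted from every channel mean
#'   before forming the ratios (default 0, i.e. frames already
#'   background-subtracted).
#' @return Scalar G estimate (> 0).
#' @export
estimate_g_factor <- function(cal, tol = 0.05, background = 0) {
  stopifnot(inherits(cal, "calibration_pair"))
  means <- c(p0 = mean(cal$without_hwp$parallel),
             q0 = mean(cal$without_hwp$perpendicular),
             p1 = mean(cal$with_hwp$parallel),
             q1 = mean(cal$with_hwp$perpendicular)) - background
  if (any(means <= 0))
    stop("calibration channel means must be positive; got ",
         paste(sprintf("%s = %.3g", names(means), means), collapse = ", "))
  rho0 <- means[["p0"]] / means[["q0"]]
  rho1 <- means[["p1"]] / means[["q1"]]
  if (abs(rho0 / rho1 - 1) > tol)
    warning(sprintf(paste0(
      "with/without half-wave-plate ratios disagree by %.1f%% (> %.1f%%); ",
      "the calibration sample may not be isotropic or the plate not ideal"),
      100 * abs(rho0 / rho1 - 1), 100 * tol))
  sqrt(rho0 * rho1)
}
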