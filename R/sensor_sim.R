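# Forward model of an NADP+-dependent monomer/homodimer anisotropy sensor.
# NADP+ binding drives homodimerization; homo-FRET within a dimer
# depolarizes emission, so anisotropy falls from the monomer bound
# (monomer-locked control) toward the dimer bound (constitutive-dimer
# control) as the pool oxidizes.

#' Sensor photophysics and binding parameters
#'
#' Defaults are explicitly simulator choices, not measured sensor
#' constants: the monomer/dimer anisotropy bounds are plausible values for
#' a slowly rotating fluorescent-protein construct under two-photon
#' excitation (theoretical ceiling 0.57), and `k_half` is placed well
#' above the pool concentration so the dimer fraction - and hence the
#' anisotropy - responds approximately linearly to NADP+ over the full
#' pool range, matching the observed first-order character of oxidation
#' and recovery traces.
#'
#' @param r_mono Anisotropy of the monomeric sensor (upper bound; must not
#'   exceed the two-photon ceiling 0.57).
#' @param r_dimer Anisotropy of the homo-FRET dimer (lower bound).
#' @param k_half NADP+ level (in units of pool fraction) at half-maximal
#'   dimerization.
#' @param hill Cooperativity exponent (>= 1).
#' @param brightness_dimer Relative photon yield per dimer (default 2:
#'   two fluorophores per dimer).
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(r_mono = 0.40, r_dimer = 0.25, k_half = 40,
                          hill = 1, brightness_dimer = 2) {
  if (!(r_dimer < r_mono)) stop("r_dimer must be below r_mono")
  if (r_mono > 0.57) stop("r_mono exceeds the two-photon anisotropy ceiling (0.57)")
  if (k_half <= 0) stop("k_half must be positive")
  if (hill < 1) stop("hill must be >= 1")
  if (brightness_dimer <= 0) stop("brightness_dimer must be positive")
  structure(list(r_mono = r_mono, r_dimer = r_dimer, k_half = k_half,
                 hill = hill, brightness_dimer = brightness_dimer),
            class = "sensor_params")
}

#' Redox-pool kinetics of the transient-oxidation assay
#'
#' @param nadph_frac0 Initial reduced fraction NADPH/(NADPH + NADP+).
#' @param k_ox First-order oxidation rate during the oxidant phase (1/s);
#'   default `log(2)/60` (60-s depletion half-life).
#' @param k_red First-order recovery rate after washout (1/s); default
#'   `log(2)/300` (300-s recovery half-life).
#' @param equilibrium_frac Reduced fraction the pool relaxes toward after
#'   washout (default: the initial fraction, i.e. full recovery).
#' @param pool_scale Relative total NADP(H) pool size reached after the
#'   oxidative challenge (>= 1); values above 1 model stress-induced pool
#'   expansion (NAD+ kinase activity). The pool grows first-order toward
#'   `pool_scale` during the recovery phase with rate `k_red`, so the
#'   simulated trace stays continuous.
#' @param phase_bounds `c(baseline_end, oxidant_end, end)` in seconds.
#' @return An object of class `kinetics_params`.
#' @export
kinetics_params <- function(nadph_frac0 = 0.9, k_ox = log(2) / 60,
                            k_red = log(2) / 300,
                            equilibrium_frac = nadph_frac0,
                            pool_scale = 1,
                            phase_bounds = c(300, 600, 1200)) {
  if (nadph_frac0 < 0 || nadph_frac0 > 1) stop("nadph_frac0 must be in [0, 1]")
  if (equilibrium_frac < 0 || equilibrium_frac > 1)
    stop("equilibrium_frac must be in [0, 1]")
  if (k_ox < 0 || k_red < 0) stop("rates must be non-negative")
  if (pool_scale < 1) stop("pool_scale must be >= 1")
  if (length(phase_bounds) != 3L || any(diff(phase_bounds) <= 0))
    stop("phase_bounds must be three increasing times")
  structure(list(nadph_frac0 = nadph_frac0, k_ox = k_ox, k_red = k_red,
                 equilibrium_frac = equilibrium_frac, pool_scale = pool_scale,
                 phase_bounds = as.numeric(phase_bounds)),
            class = "kinetics_params")
}

#' Image-formation parameters of the simulator
#'
#' @param photons_per_pixel Expected total emission counts per pixel at
#'   unit sensor expression.
#' @param background_counts Additive detector offset per channel (counts).
#' @param g_factor_true Simulated channel imbalance: the perpendicular
#'   channel is detected with efficiency `1/g_factor_true` relative to the
#'   parallel channel.
#' @param numerical_aperture,refractive_index Objective model used for
#'   forward polarization mixing.
#' @param scatter_alpha_per_um Depolarized-photon mixing fraction per um
#'   of imaging depth; `scatter_alpha_per_um * depth` must stay below 1.
#' @param poisson_noise Apply photon (shot) noise (default TRUE).
#' @param seed Optional RNG seed applied by the rendering functions.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(photons_per_pixel = 2e4, background_counts = 50,
                           g_factor_true = 1.25, numerical_aperture = 1.3,
                           refractive_index = 1.518,
                           scatter_alpha_per_um = 0.005,
                           poisson_noise = TRUE, seed = NULL) {
  if (photons_per_pixel <= 0) stop("photons_per_pixel must be positive")
  if (background_counts < 0) stop("background_counts must be non-negative")
  if (g_factor_true <= 0) stop("g_factor_true must be positive")
  if (scatter_alpha_per_um < 0) stop("scatter_alpha_per_um must be non-negative")
  compute_na_factors(numerical_aperture, refractive_index)  # validates the pair
  structure(list(photons_per_pixel = photons_per_pixel,
                 background_counts = background_counts,
                 g_factor_true = g_factor_true,
                 numerical_aperture = numerical_aperture,
                 refractive_index = refractive_index,
                 scatter_alpha_per_um = scatter_alpha_per_um,
                 poisson_noise = poisson_noise, seed = seed),
            class = "imaging_params")
}

#' Dimer fraction as a function of NADP+ level
#'
#' Hill response of allosteric dimerization:
#' \deqn{f_d = \frac{x^h}{K_{1/2}^h + x^h}}
#' with `x` the NADP+ level in pool-fraction units and `h` the Hill
#' exponent. Monotone increasing, 0 at `x = 0`, 1/2 at `x = k_half`.
#'
#' @param nadp_frac NADP+ level (vectorized), in pool-fraction units.
#' @param params A [sensor_params()].
#' @return Dimer fraction in \[0, 1).
#' @export
dimer_fraction <- function(nadp_frac, params) {
  stopifnot(inherits(params, "sensor_params"))
  if (any(nadp_frac < 0)) stop("nadp_frac must be non-negative")
  x <- nadp_frac^params$hill
  x / (params$k_half^params$hill + x)
}

#' Ensemble anisotropy of a monomer/dimer mixture
#'
#' Steady-state anisotropy of a mixture is additive with fractional
#' photon-contribution weights. With dimers `brightness_dimer` times as
#' bright as monomers,
#' \deqn{w_d = \frac{b f_d}{b f_d + (1 - f_d)}, \qquad
#'       r = w_d r_{dimer} + (1 - w_d) r_{mono},}
#' giving `r_mono` at `f_d = 0`, `r_dimer` at `f_d = 1`, and a monotone
#' decrease in between.
#'
#' @param f_d Dimer fraction in \[0, 1\] (vectorized).
#' @param params A [sensor_params()].
#' @return Ensemble anisotropy.
#' @export
ensemble_anisotropy <- function(f_d, params) {
  stopifnot(inherits(params, "sensor_params"))
  if (any(f_d < 0 | f_d > 1)) stop("f_d must be in [0, 1]")
  b <- params$brightness_dimer
  w <- b * f_d / (b * f_d + (1 - f_d))
  w * params$r_dimer + (1 - w) * params$r_mono
}

#' Closed-form redox-pool kinetics
#'
#' Piecewise first-order dynamics of the reduced fraction: constant at
#' `nadph_frac0` during the baseline; exponential decay toward 0 with rate
#' `k_ox` while the oxidant is present; exponential relaxation toward
#' `equilibrium_frac` with rate `k_red` after washout. Continuous at both
#' phase boundaries.
#'
#' @param params A [kinetics_params()].
#' @param times Numeric vector of times (s) within `[0, phase_bounds[3]]`.
#' @return Reduced fraction NADPH/(NADPH + NADP+) at `times`.
#' @export
simulate_kinetics <- function(params, times) {
  stopifnot(inherits(params, "kinetics_params"))
  b <- params$phase_bounds
  if (any(times < 0 | times > b[3]))
    stop("times must lie within [0, ", b[3], "] s")
  n1 <- params$nadph_frac0
  n2 <- n1 * exp(-params$k_ox * (b[2] - b[1]))  # value at washout
  ifelse(times < b[1], n1,
    ifelse(times < b[2],
           n1 * exp(-params$k_ox * (times - b[1])),
           params$equilibrium_frac +
             (n2 - params$equilibrium_frac) * exp(-params$k_red * (times - b[2]))))
}

#' Relative total-pool size over the assay
#'
#' Unity through baseline and oxidation; grows first-order toward
#' `pool_scale` with rate `k_red` during recovery (the modeled NAD+ kinase
#' pool-expansion signature). Identically 1 when `pool_scale = 1`.
#'
#' @param params A [kinetics_params()].
#' @param times Numeric vector of times (s).
#' @return Relative pool size at `times`.
#' @export
pool_trace <- function(params, times) {
  stopifnot(inherits(params, "kinetics_params"))
  b <- params$phase_bounds
  ifelse(times < b[2], 1,
         1 + (params$pool_scale - 1) * (1 - exp(-params$k_red * (times - b[2]))))
}

#' Sensor anisotropy implied by a reduced fraction
#'
#' Chains the sensor transfer: NADP+ level `(1 - nadph_frac) * pool`,
#' Hill dimerization, brightness-weighted ensemble anisotropy.
#'
#' @param nadph_frac Reduced fraction (vectorized).
#' @param sensor A [sensor_params()].
#' @param pool Relative pool size (default 1; vectorized).
#' @return Ensemble anisotropy.
#' @export
sensor_anisotropy <- function(nadph_frac, sensor, pool = 1) {
  f <- dimer_fraction((1 - nadph_frac) * pool, sensor)
  ensemble_anisotropy(f, sensor)
}

#' Depth-dependent scatter depolarization
#'
#' Models tissue scatter as depth-proportional replacement of polarized
#' photons by fully depolarized ones: a fraction
#' `alpha = scatter_alpha_per_um * depth` of detected photons carries zero
#' anisotropy, so the observed anisotropy is `(1 - alpha) * r_true`.
#' Absolute anisotropy declines with depth while the dynamic range between
#' two sensors shrinks by exactly `(1 - alpha)`.
#'
#' @param r_true True anisotropy (vectorized).
#' @param depth_um Imaging depth in um.
#' @param params An [imaging_params()].
#' @return Observed anisotropy.
#' @export
apply_depth_scatter <- function(r_true, depth_um, params) {
  stopifnot(inherits(params, "imaging_params"))
  alpha <- params$scatter_alpha_per_um * depth_um
  if (any(alpha >= 1))
    stop("scatter fraction reaches 1 at this depth; reduce scatter_alpha_per_um")
  (1 - alpha) * r_true
}
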