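# Independent oracle for the aperture factors: 2-D numerical quadrature of
# the collection-cone integrals of dipole far-field radiation. The detected
# x-polarized field of a dipole (mu_x, mu_y, mu_z), for a ray at polar angle
# psi and azimuth phi after collimation, is
#   E_x = mu_x (cos psi cos^2 phi + sin^2 phi)
#       + mu_y cos phi sin phi (cos psi - 1) - mu_z sin psi cos phi,
# and integrating E_x^2 sin psi over the cone gives
#   I_x = Kb mu_x^2 + Kc mu_y^2 + Ka mu_z^2   (x pi, which normalizes away).
quadrature_na_factors <- function(na, ri) {
  theta <- asin(na / ri)
  ka <- pracma::integral2(function(psi, phi)
    (sin(psi) * cos(phi))^2 * sin(psi),
    0, theta, 0, 2 * pi, reltol = 1e-12)$Q / pi
  kb <- pracma::integral2(function(psi, phi)
    (cos(psi) * cos(phi)^2 + sin(phi)^2)^2 * sin(psi),
    0, theta, 0, 2 * pi, reltol = 1e-12)$Q / pi
  kc <- pracma::integral2(function(psi, phi)
    (cos(phi) * sin(phi) * (cos(psi) - 1))^2 * sin(psi),
    0, theta, 0, 2 * pi, reltol = 1e-12)$Q / pi
  c(ka = ka, kb = kb, kc = kc)
}

test_that("closed-form aperture factors match numerical quadrature", {
  for (na in c(0.5, 1.0, 1.3, 1.4)) {
    ri <- if (na > 1.33) 1.518 else 1.518
    expect_equal(compute_na_factors(na, ri), quadrature_na_factors(na, ri),
                 tolerance = 1e-8)
  }
  # water immersion too
  expect_equal(compute_na_factors(1.0, 1.33), quadrature_na_factors(1.0, 1.33),
               tolerance = 1e-8)
})

test_that("aperture mixing vanishes in the paraxial limit and grows with NA", {
  m <- na_mixing_matrix(optics_config(1, 1e-4, 1.518))
  expect_lt(max(abs(m - diag(2))), 1e-8)
  # relative mixing strictly larger at NA = 1.0 than at NA = 0.5
  k05 <- compute_na_factors(0.5, 1.518)
  k10 <- compute_na_factors(1.0, 1.518)
  expect_gt((k10[["kc"]] + k10[["ka"]]) / k10[["kb"]],
            (k05[["kc"]] + k05[["ka"]]) / k05[["kb"]])
  expect_gt(k10[["kc"]] / k10[["kb"]], k05[["kc"]] / k05[["kb"]])
  # invalid regimes
  expect_error(compute_na_factors(1.518, 1.518), "smaller than")
  expect_error(compute_na_factors(-0.1, 1.518), "positive")
})

test_that("forward mixing then correction is the identity to 1e-9", {
  fr <- tiny_frame(300, 100)
  for (g in c(1, 1.25)) {
    optics <- optics_config(g, 1.3, 1.518)
    mixed <- apply_na_mixing(fr, optics)
    rec <- apply_na_correction(mixed, optics)
    expect_lt(max(abs(rec$parallel - 300)), 1e-9)
    expect_lt(max(abs(rec$perpendicular - 100)), 1e-9)
  }
})

test_that("the NA correction is a linear operator", {
  optics <- default_optics()
  fr <- random_frame(seed = 5)
  one <- apply_na_correction(fr, optics)
  fr2 <- fr; fr2$parallel <- 2 * fr$parallel
  fr2$perpendicular <- 2 * fr$perpendicular
  two <- apply_na_correction(fr2, optics)
  expect_equal(two$parallel, 2 * one$parallel, tolerance = 1e-12)
  expect_equal(two$perpendicular, 2 * one$perpendicular, tolerance = 1e-12)
})

test_that("G-factor estimation inverts a simulated detection bias", {
  # unbiased system: both ratios 1, G = 1
  iso <- function(g, seed = NULL, noise = FALSE, photons = 1e4)
    simulate_calibration_pair(
      imaging_params(photons_per_pixel = photons, background_counts = 0,
                     g_factor_true = g, poisson_noise = noise),
      shape = c(32, 32), seed = seed)
  expect_equal(estimate_g_factor(iso(1)), 1, tolerance = 1e-12)
  # perpendicular path scaled by 0.8 => true G = 1.25, recovered exactly
  expect_equal(estimate_g_factor(iso(1.25)), 1.25, tolerance = 1e-6)
  # Poisson noise at 1e4 counts/pixel: within 1% across 20 seeds
  gs <- vapply(1:20, function(s)
    estimate_g_factor(iso(1.25, seed = s, noise = TRUE)), numeric(1))
  expect_true(all(abs(gs / 1.25 - 1) < 0.01))
})

test_that("geometric-mean G estimate cancels residual sample anisotropy", {
  # paraxial acquisition isolates the detector-path bias from aperture mixing
  img <- imaging_params(photons_per_pixel = 1e4, background_counts = 0,
                        g_factor_true = 1.25, numerical_aperture = 1e-4,
                        poisson_noise = FALSE)
  cal <- simulate_calibration_pair(img, shape = c(16, 16),
                                   sample_anisotropy = 0.02)
  expect_equal(suppressWarnings(estimate_g_factor(cal)), 1.25,
               tolerance = 1e-9)
})

test_that("inconsistent or degenerate calibration input is flagged", {
  f0 <- tiny_frame(100, 100)
  f1 <- tiny_frame(100, 50)  # with-plate ratio 2 vs without-plate ratio 1
  expect_warning(estimate_g_factor(calibration_pair(f1, f0)), "disagree")
  fz <- tiny_frame(100, 0)
  expect_error(estimate_g_factor(calibration_pair(fz, fz)), "positive")
})

test_that("calibration closure: isotropic sample reads r = 0 under estimated G", {
  img <- imaging_params(photons_per_pixel = 1e4, background_counts = 0,
                        g_factor_true = 1.25, poisson_noise = FALSE)
  cal <- simulate_calibration_pair(img, shape = c(32, 32))
  g <- estimate_g_factor(cal)
  optics <- optics_config(g, img$numerical_aperture, img$refractive_index)
  r0 <- mean_roi(compute_anisotropy(
    apply_na_correction(cal$without_hwp, optics), optics))
  expect_lt(abs(r0), 1e-6)
  # same closure with photon noise: within 1e-2
  cal_n <- simulate_calibration_pair(
    imaging_params(photons_per_pixel = 1e4, background_counts = 0,
                   g_factor_true = 1.25), shape = c(32, 32), seed = 3)
  g_n <- estimate_g_factor(cal_n)
  optics_n <- optics_config(g_n, img$numerical_aperture, img$refractive_index)
  r0_n <- mean_roi(compute_anisotropy(
    apply_na_correction(cal_n$without_hwp, optics_n), optics_n))
  expect_lt(abs(r0_n), 1e-2)
})
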