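test_that("rendering with ideal optics is exactly inverted by the r formula", {
  ph <- flat_phantom()
  img <- imaging_params(photons_per_pixel = 3000, background_counts = 0,
                        g_factor_true = 1, numerical_aperture = 1e-6,
                        poisson_noise = FALSE)
  r_field <- matrix(seq(0.25, 0.40, length.out = 256), 16, 16)
  st <- render_stack(ph, r_field, img, axis_kind = "z")
  map <- compute_anisotropy(st$frames[[1]], optics_config(1, 1e-6, 1.518))
  expect_lt(max(abs(map$r[map$mask] - r_field[map$mask])), 1e-10)
})

test_that("the full processing chain inverts the realistic forward model", {
  ph <- make_phantom(c(48, 48), n_cells = 25, seed = 6)
  img <- imaging_params(background_counts = 50, g_factor_true = 1.25,
                        numerical_aperture = 1.3, poisson_noise = FALSE)
  r_field <- matrix(0.32, 48, 48)
  st <- render_stack(ph, r_field, img, axis_kind = "z")
  map <- process_frame(st$frames[[1]], default_optics(1.25),
                       preprocess_config(background = 50))
  expect_lt(max(abs(map$r[map$mask] - 0.32)), 1e-9)
})

test_that("Poisson rendering is unbiased over many pixels of constant r", {
  ph <- flat_phantom(c(100, 100))
  img <- imaging_params(photons_per_pixel = 5000, background_counts = 0,
                        g_factor_true = 1, numerical_aperture = 1e-6,
                        poisson_noise = TRUE, seed = 17)
  r0 <- 0.3
  st <- render_stack(ph, matrix(r0, 100, 100), img, axis_kind = "z")
  map <- compute_anisotropy(st$frames[[1]], optics_config(1, 1e-6, 1.518))
  vals <- map$r[map$mask]
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - r0), 3 * sem)
})

test_that("stochastic outputs are bit-reproducible under a fixed seed", {
  ph <- make_phantom(c(32, 32), seed = 4)
  img <- imaging_params(seed = 21)
  a <- render_stack(ph, list(0.3, 0.35), img, axis_kind = "time")
  b <- render_stack(ph, list(0.3, 0.35), img, axis_kind = "time")
  expect_identical(a, b)
  sim1 <- simulate_assay(sensor_params(), kinetics_params(), img,
                         make_phantom(c(24, 24), seed = 9), seed = 31)
  sim2 <- simulate_assay(sensor_params(), kinetics_params(), img,
                         make_phantom(c(24, 24), seed = 9), seed = 31)
  expect_identical(sim1$stack, sim2$stack)
})

test_that("noise-free simulated assays reproduce their analytic ground truth", {
  ph <- make_phantom(c(40, 40), seed = 2)
  img <- imaging_params(poisson_noise = FALSE)
  res <- simulate_assay(sensor_params(), kinetics_params(), img, ph)
  maps <- process_stack(res$stack, default_optics(img$g_factor_true),
                        preprocess_config(background = img$background_counts))
  tr <- build_trace(maps, res$times)
  # every time point matches the true (depth-attenuated) anisotropy
  expect_lt(max(abs(tr$r_mean - res$truth_trace$r_mean)), 1e-9)
  m <- assay_metrics(tr)
  # fitted boundary values differ from single-sample truth only through the
  # small curvature of the sensor transfer
  expect_lt(abs(m$diamide_drop - res$truth_metrics$diamide_drop),
            0.05 * abs(res$truth_metrics$diamide_drop))
  expect_lt(abs(m$baseline_change - res$truth_metrics$baseline_change), 1e-3)
})

test_that("locked control sensors give flat traces under the oxidation protocol", {
  ph <- make_phantom(c(40, 40), seed = 8)
  img <- imaging_params(poisson_noise = FALSE)
  for (lock in c("monomer", "dimer")) {
    res <- simulate_assay(sensor_params(), kinetics_params(), img, ph,
                          lock = lock)
    expect_lt(diff(range(res$truth_trace$r_mean)), 1e-12)
  }
})

test_that("an equilibrium matching the baseline gives zero true baseline change", {
  # fast recovery so relaxation back to the baseline completes within the assay
  res <- simulate_assay(sensor_params(),
                        kinetics_params(equilibrium_frac = 0.9,
                                        k_red = log(2) / 60),
                        imaging_params(poisson_noise = FALSE),
                        make_phantom(c(24, 24), seed = 3))
  expect_lt(abs(res$truth_metrics$baseline_change), 1e-5)
  expect_equal(res$truth_metrics$depletion_half_life_s, 60)
  expect_equal(res$truth_metrics$recovery_half_life_s, 60)
})
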