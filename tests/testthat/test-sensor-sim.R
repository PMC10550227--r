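test_that("dimer fraction follows the Hill response", {
  sp <- sensor_params(k_half = 0.3, hill = 1)
  expect_equal(dimer_fraction(0, sp), 0)
  expect_equal(dimer_fraction(0.3, sp), 0.5)  # half-saturation definition
  # hill = 2 is steeper around k_half and matches direct evaluation
  sp2 <- sensor_params(k_half = 0.3, hill = 2)
  x <- c(0.1, 0.3, 0.6, 0.9)
  expect_equal(dimer_fraction(x, sp2), x^2 / (0.3^2 + x^2), tolerance = 1e-15)
  expect_gt(dimer_fraction(0.6, sp2), dimer_fraction(0.6, sp))
  # monotone increasing
  f <- dimer_fraction(seq(0, 1, 0.05), sp)
  expect_true(all(diff(f) > 0))
})

test_that("ensemble anisotropy interpolates the monomer and dimer bounds", {
  sp <- sensor_params(r_mono = 0.4, r_dimer = 0.25, brightness_dimer = 2)
  expect_equal(ensemble_anisotropy(0, sp), 0.4)
  expect_equal(ensemble_anisotropy(1, sp), 0.25)
  # photon-weighted mixture: f = 0.5 with 2x dimer brightness
  expect_equal(ensemble_anisotropy(0.5, sp), (2 * 0.25 + 0.4) / 3)
  # monotone decreasing in dimer fraction
  r <- ensemble_anisotropy(seq(0, 1, 0.05), sp)
  expect_true(all(diff(r) < 0))
})

test_that("ensemble mixing matches a photon-level Monte-Carlo mixture", {
  sp <- sensor_params(r_mono = 0.4, r_dimer = 0.25, brightness_dimer = 2)
  f_d <- 0.5
  n_phot <- 1e6
  set.seed(99)
  w_d <- 2 * f_d / (2 * f_d + (1 - f_d))  # photon from a dimer
  from_dimer <- runif(n_phot) < w_d
  r_src <- ifelse(from_dimer, 0.25, 0.4)
  # each emitted photon occupies one of three polarization modes:
  # parallel with prob (1+2r)/3, or one of the two perpendicular-equivalent
  # modes with prob (1-r)/3 each (only one of which the I-perp channel sees)
  u <- runif(n_phot)
  p <- sum(u < (1 + 2 * r_src) / 3)
  q <- sum(u >= (1 + 2 * r_src) / 3 & u < (2 + r_src) / 3)
  r_mc <- (p - q) / (p + 2 * q)
  r_th <- ensemble_anisotropy(f_d, sp)
  # 3 sigma of the photon-counting estimate of r
  sigma <- sqrt((1 - r_th) * (1 + 2 * r_th) * (2 + r_th) / (3 * n_phot))
  expect_lt(abs(r_mc - r_th), 3 * sigma)
})

test_that("piecewise kinetics honor the closed forms and an ODE oracle", {
  kp <- kinetics_params(nadph_frac0 = 0.9, k_ox = log(2) / 60,
                        k_red = log(2) / 300, equilibrium_frac = 0.9)
  # null dynamics
  kp0 <- kinetics_params(k_ox = 0, k_red = 0)
  t <- seq(0, 1200, 10)
  expect_equal(simulate_kinetics(kp0, t), rep(0.9, length(t)))
  # half-life definition: value at 360 s is half of the 300-s value
  expect_equal(simulate_kinetics(kp, 360), 0.9 / 2, tolerance = 1e-12)
  # independent oracle: numerical integration of the same piecewise ODE
  rate <- function(t, y, parms) {
    dy <- if (t < 300) 0
          else if (t < 600) -kp$k_ox * y
          else -kp$k_red * (y - kp$equilibrium_frac)
    list(dy)
  }
  ode <- deSolve::ode(y = c(n = 0.9), times = t, func = rate, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(ode[, "n"] - simulate_kinetics(kp, t))), 1e-6)
  # continuity at the phase boundaries
  eps <- 1e-9
  expect_equal(simulate_kinetics(kp, 300 - eps), simulate_kinetics(kp, 300 + eps),
               tolerance = 1e-6)
  expect_equal(simulate_kinetics(kp, 600 - eps), simulate_kinetics(kp, 600 + eps),
               tolerance = 1e-6)
})

test_that("depth scatter rescales anisotropy and the dynamic range by 1 - alpha", {
  img <- imaging_params(scatter_alpha_per_um = 0.005)
  expect_equal(apply_depth_scatter(0.35, 0, img), 0.35)
  expect_equal(apply_depth_scatter(0, 25, img), 0)
  expect_equal(apply_depth_scatter(0.35, 40, img), 0.8 * 0.35)
  sp <- sensor_params()
  depths <- seq(0, 40, 5)
  hi <- apply_depth_scatter(rep(sp$r_mono, length(depths)), depths, img)
  lo <- apply_depth_scatter(rep(sp$r_dimer, length(depths)), depths, img)
  expect_true(all(diff(hi) < 0))
  expect_equal((hi - lo) / (sp$r_mono - sp$r_dimer),
               1 - 0.005 * depths, tolerance = 1e-12)
  expect_error(apply_depth_scatter(0.3, 250, img), "reaches 1")
})

test_that("pool expansion produces the negative baseline-change signature", {
  sp <- sensor_params()
  # fast recovery so the redox state itself fully re-equilibrates by 20 min
  base <- kinetics_params(k_red = log(2) / 60)
  exp15 <- kinetics_params(k_red = log(2) / 60, pool_scale = 1.5)
  t <- c(300, 1200)
  r_base <- sensor_anisotropy(simulate_kinetics(base, t), sp,
                              pool_trace(base, t))
  r_exp <- sensor_anisotropy(simulate_kinetics(exp15, t), sp,
                             pool_trace(exp15, t))
  expect_lt(abs(r_base[2] - r_base[1]), 1e-5)
  expect_lt(r_exp[2] - r_exp[1], -2e-4)
})

test_that("phantoms are seed-reproducible with lognormal cell expression", {
  a <- make_phantom(c(64, 64), n_cells = 30, seed = 12)
  b <- make_phantom(c(64, 64), n_cells = 30, seed = 12)
  expect_identical(a, b)
  expect_true(all(a$expression[!a$support] == 0))
  # single cell: uniform positive expression over the support
  u <- make_phantom(c(32, 32), n_cells = 1, seed = 2)
  vals <- unique(u$expression[u$support])
  expect_length(vals, 1)
  expect_gt(vals, 0)
  # per-cell expression consistent with the specified lognormal in >= 19/20 seeds
  pass <- vapply(1:20, function(s) {
    ph <- make_phantom(c(96, 96), n_cells = 200, seed = s, sdlog = 0.4)
    lv <- vapply(split(ph$expression[ph$support], ph$cell_labels[ph$support]),
                 function(v) v[1], numeric(1))
    suppressWarnings(stats::ks.test(lv, stats::plnorm, 0, 0.4)$p.value) > 0.05
  }, logical(1))
  expect_gte(sum(pass), 19)
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(123); x1 <- runif(3)
  set.seed(123); invisible(make_phantom(seed = 5)); x2 <- runif(3)
  expect_identical(x1, x2)
})
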