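test_that("ROI means follow direct arithmetic", {
  uni <- map_with_n_valid(3600, 0.3)
  roi <- roi_spec("any", rbind(c(1, 1), c(2, 2), c(3, 5)), dims = c(60, 60))
  expect_equal(mean_roi(uni, roi), 0.3)
  # two-pixel ROI averaging distinct values
  r <- matrix(NA_real_, 4, 4); mask <- matrix(FALSE, 4, 4)
  r[1, 1] <- 0.2; r[2, 2] <- 0.4; mask[1, 1] <- mask[2, 2] <- TRUE
  m <- anisotropy_map(r, mask)
  expect_equal(mean_roi(m, roi_spec("two", rbind(c(1, 1), c(2, 2)),
                                    dims = c(4, 4))), 0.3)
  # random map + random ROI vs brute-force loop
  set.seed(14)
  mask <- matrix(runif(400) < 0.7, 20, 20)
  r <- matrix(NA_real_, 20, 20); r[mask] <- runif(sum(mask), -0.1, 0.4)
  map <- anisotropy_map(r, mask)
  roi_px <- matrix(runif(400) < 0.5, 20, 20)
  acc <- c()
  for (i in 1:20) for (j in 1:20)
    if (mask[i, j] && roi_px[i, j]) acc <- c(acc, r[i, j])
  expect_equal(mean_roi(map, roi_spec("rand", roi_px)), mean(acc))
  # empty intersection errors
  off <- roi_spec("off", rbind(c(1, 2)), dims = c(4, 4))
  expect_error(mean_roi(m, off), "intersect")
})

test_that("z-stack pooling excludes slices below the 1000-pixel rule", {
  maps <- list(map_with_n_valid(2000, 0.2), map_with_n_valid(500, 0.9),
               map_with_n_valid(3000, 0.3))
  # slice 2 (r = 0.9) must not contribute
  expect_equal(aggregate_zstack(maps),
               (2000 * 0.2 + 3000 * 0.3) / 5000)
  # uniform field is returned unchanged
  uni <- lapply(c(2000, 1500, 3000), map_with_n_valid, r0 = 0.25)
  expect_equal(aggregate_zstack(uni), 0.25)
  # no surviving slice
  expect_error(aggregate_zstack(list(map_with_n_valid(10, 0.2))), "1000")
})

test_that("pooling equals the brute-force mean over qualifying pixels", {
  set.seed(3)
  maps <- lapply(c(1400, 800, 2100), function(n) {
    mask <- matrix(FALSE, 60, 60); mask[seq_len(n)] <- TRUE
    r <- matrix(NA_real_, 60, 60); r[mask] <- runif(n, 0.1, 0.4)
    anisotropy_map(r, mask)
  })
  pooled <- c(maps[[1]]$r[maps[[1]]$mask], maps[[3]]$r[maps[[3]]$mask])
  expect_equal(aggregate_zstack(maps), mean(pooled))
  # consistency: identical to the n_valid-weighted mean of slice means
  expect_equal(aggregate_zstack(maps),
               (mean_roi(maps[[1]]) * maps[[1]]$n_valid +
                mean_roi(maps[[3]]) * maps[[3]]$n_valid) /
                 (maps[[1]]$n_valid + maps[[3]]$n_valid))
})

test_that("traces assemble per-time-point slice means with phase bounds", {
  maps <- lapply(seq(0.30, 0.20, length.out = 121), map_with_n_valid,
                 n_valid = 1500)
  tr <- build_trace(maps, seq(0, 1200, by = 10))
  expect_s3_class(tr, "assay_trace")
  expect_length(tr$time_s, 121)
  expect_equal(tr$phase_bounds, c(300, 600, 1200))
  expect_equal(tr$r_mean[1], 0.30)
  expect_equal(tr$n_valid[5], 1500)
  # single time point: degenerate but valid trace
  tr1 <- build_trace(maps[1], 0)
  expect_length(tr1$time_s, 1)
  # permuted times violate the contract
  expect_error(build_trace(maps[1:3], c(0, 20, 10)), "increasing")
})

test_that("delta-referencing zeroes the reference point and is idempotent", {
  tr <- synthetic_trace()
  d1 <- delta_trace(tr, 300)
  expect_equal(stats::approx(d1$time_s, d1$r_mean, xout = 300)$y, 0)
  d2 <- delta_trace(d1, 300)
  expect_equal(d1$r_mean, d2$r_mean)
  # pairwise differences survive the shift
  expect_equal(diff(d1$r_mean), diff(tr$r_mean))
  expect_error(delta_trace(tr, 5000), "outside")
})

test_that("delta-referencing preserves all four assay metrics exactly", {
  tr <- synthetic_trace(noise_sd = 0.002, seed = 4)
  m0 <- assay_metrics(tr)
  m1 <- assay_metrics(delta_trace(tr, 300))
  expect_equal(m1$diamide_drop, m0$diamide_drop, tolerance = 1e-8)
  expect_equal(m1$depletion_half_life_s, m0$depletion_half_life_s,
               tolerance = 1e-6)
  expect_equal(m1$recovery_half_life_s, m0$recovery_half_life_s,
               tolerance = 1e-6)
  expect_equal(m1$baseline_change, m0$baseline_change, tolerance = 1e-8)
})
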