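# Shared fixture builders. Everything is generated in code; no image files
# ship with the package.

tiny_frame <- function(p, q, ...) {
  polarized_frame(matrix(p, 2, 2), matrix(q, 2, 2), ...)
}

random_frame <- function(nr = 12, nc = 10, seed = 1, max_counts = 1000) {
  set.seed(seed)
  polarized_frame(
    matrix(sample.int(max_counts, nr * nc, replace = TRUE), nr, nc),
    matrix(sample.int(max_counts, nr * nc, replace = TRUE), nr, nc))
}

# anisotropy map with an exact valid-pixel count, uniform value r0
map_with_n_valid <- function(n_valid, r0, dims = c(60, 60)) {
  mask <- matrix(FALSE, dims[1], dims[2])
  mask[seq_len(n_valid)] <- TRUE
  r <- matrix(NA_real_, dims[1], dims[2])
  r[mask] <- r0
  anisotropy_map(r, mask)
}

default_optics <- function(g = 1.25) optics_config(g, 1.3, 1.518)

# noise-free imaging with flat unit expression for exact-arithmetic tests
flat_phantom <- function(shape = c(16, 16)) {
  ph <- make_phantom(shape, n_cells = 1, seed = 1, sdlog = 0)
  ph$expression[ph$support] <- 1
  ph
}

# synthetic assay trace from closed-form phase curves
synthetic_trace <- function(baseline = 0.35, drop_amp = 0.15, tau_dep = 90,
                            rec_amp = drop_amp, tau_rec = 300, dt = 10,
                            bounds = c(300, 600, 1200), noise_sd = 0,
                            seed = NULL) {
  t <- seq(0, bounds[3], by = dt)
  plateau_dep <- baseline - drop_amp
  r <- ifelse(t < bounds[1], baseline,
       ifelse(t < bounds[2],
              plateau_dep + drop_amp * exp(-(t - bounds[1]) / tau_dep),
              {
                r600 <- plateau_dep + drop_amp * exp(-(bounds[2] - bounds[1]) / tau_dep)
                (r600 + rec_amp) - rec_amp * exp(-(t - bounds[2]) / tau_rec)
              }))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    r <- r + rnorm(length(r), 0, noise_sd)
  }
  assay_trace(t, r, phase_bounds = bounds)
}
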