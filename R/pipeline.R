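# Pipeline orchestration over a single YAML config with sections
#   optics / preprocess / assay / simulate / io
# Each run_* writes its outputs under io$output_dir together with a
# resolved-config echo (YAML) sufficient to reproduce the run.

abort <- function(msg, class) stop(errorCondition(msg, class = c(class, "error")))

#' Read and validate a pipeline configuration file
#'
#' @param path YAML config path, or a pre-parsed list.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path))
      abort(paste0("config file not found: ", path), "anisokit_validation_error")
    yaml::read_yaml(path)
  }
  cfg$optics <- utils::modifyList(
    list(g_factor = 1, numerical_aperture = 1.3, refractive_index = 1.518),
    cfg$optics %||% list())
  cfg$preprocess <- utils::modifyList(
    list(background = 0, lower_fraction = 0.05, upper_fraction = 0.05,
         threshold_mode = "range"),
    cfg$preprocess %||% list())
  cfg$assay <- utils::modifyList(
    list(phase_bounds = c(300, 600, 1200), use_fits = TRUE, min_pixels = 1000),
    cfg$assay %||% list())
  cfg$io <- cfg$io %||% list()
  cfg$io$output_dir <- cfg$io$output_dir %||% "."
  # construct once to surface invalid numeric fields early
  do.call(optics_config, cfg$optics)
  do.call(preprocess_config, cfg$preprocess)
  structure(cfg, class = "pipeline_config")
}

resolve_cfg <- function(cfg) {
  if (inherits(cfg, "pipeline_config")) cfg else read_pipeline_config(cfg)
}

write_provenance <- function(cfg, dir, step) {
  prov <- unclass(cfg)
  prov$.step <- step
  prov$.package_version <- as.character(utils::packageVersion("anisokit"))
  yaml::write_yaml(prov, file.path(dir, paste0(step, "_config.yaml")))
}

sim_objects <- function(sim) {
  list(
    sensor = do.call(sensor_params, sim$sensor %||% list()),
    kinetics = do.call(kinetics_params, sim$kinetics %||% list()),
    imaging = do.call(imaging_params, sim$imaging %||% list()),
    phantom = do.call(make_phantom, utils::modifyList(
      list(seed = sim$seed %||% 1), sim$phantom %||% list())))
}

#' Run the `simulate` pipeline step
#'
#' Renders a synthetic assay time series from the `simulate` config
#' section and writes the polarized stack (TIFF + sidecar), the
#' ground-truth trace (`truth_trace.csv`), the ground-truth metrics
#' (`truth_metrics.csv`) and a resolved-config echo.
#'
#' @param cfg Config path or [read_pipeline_config()] result.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(cfg) {
  cfg <- resolve_cfg(cfg)
  if (is.null(cfg$simulate))
    abort("config has no `simulate` section", "anisokit_validation_error")
  sim <- cfg$simulate
  dir.create(cfg$io$output_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- sim_objects(sim)
  obj$imaging$seed <- sim$seed %||% 1
  res <- simulate_assay(obj$sensor, obj$kinetics, obj$imaging, obj$phantom,
                        dt = sim$dt %||% 10, depth_um = sim$depth_um %||% 12,
                        lock = sim$lock)
  paths <- list(
    stack = file.path(cfg$io$output_dir, "simulated_stack.tif"),
    trace = file.path(cfg$io$output_dir, "truth_trace.csv"),
    metrics = file.path(cfg$io$output_dir, "truth_metrics.csv"))
  write_polarized_stack(res$stack, paths$stack)
  write_trace_csv(res$truth_trace, paths$trace)
  utils::write.csv(as.data.frame(res$truth_metrics), paths$metrics,
                   row.names = FALSE)
  write_provenance(cfg, cfg$io$output_dir, "simulate")
  message(sprintf("simulate: wrote %d-frame stack (seed %s)",
                  length(res$stack), format(obj$imaging$seed)))
  invisible(paths)
}

#' Run the `gfactor` pipeline step
#'
#' Reads a calibration TIFF (a 2-frame stack: frame 1 without the
#' half-wave plate, frame 2 with it), estimates G, reports the residual
#' anisotropy of the calibration sample under the estimate, and writes
#' both to `gfactor.csv`.
#'
#' @param cfg Config path or [read_pipeline_config()] result; uses
#'   `io$calibration`.
#' @return The G estimate, invisibly.
#' @export
run_gfactor <- function(cfg) {
  cfg <- resolve_cfg(cfg)
  if (is.null(cfg$io$calibration))
    abort("config has no io$calibration path", "anisokit_validation_error")
  st <- read_polarized_stack(cfg$io$calibration)
  if (length(st$frames) != 2L)
    abort("calibration stack must hold exactly 2 frames (without, with plate)",
          "anisokit_validation_error")
  cal <- calibration_pair(without_hwp = st$frames[[1]], with_hwp = st$frames[[2]])
  bg <- cfg$preprocess$background %||% 0
  g <- estimate_g_factor(cal, background = mean(bg))
  opt <- optics_config(g, cfg$optics$numerical_aperture,
                       cfg$optics$refractive_index)
  prep <- do.call(preprocess_config, cfg$preprocess)
  f <- apply_na_correction(subtract_background(st$frames[[1]], prep), opt)
  resid <- mean_roi(compute_anisotropy(f, opt))
  dir.create(cfg$io$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(g_factor = g, residual_anisotropy = resid),
                   file.path(cfg$io$output_dir, "gfactor.csv"),
                   row.names = FALSE)
  message(sprintf("gfactor: G = %.6g, residual isotropic anisotropy %.3g",
                  g, resid))
  invisible(g)
}

#' Run the `process` pipeline step
#'
#' Reads the input stack, runs the per-frame preprocessing and anisotropy
#' chain, and writes a per-frame summary (`frame_summary.csv`: frame
#' index, axis coordinate, mean r, valid-pixel count) plus, when
#' `io$write_maps` is true, one float TIFF anisotropy map (and mask) per
#' frame. G comes from `optics$g_factor`, or is estimated from
#' `io$calibration` when that is set.
#'
#' @param cfg Config path or [read_pipeline_config()] result.
#' @return Invisibly, the per-frame summary data frame.
#' @export
run_process <- function(cfg) {
  cfg <- resolve_cfg(cfg)
  if (is.null(cfg$io$stack))
    abort("config has no io$stack path", "anisokit_validation_error")
  stack <- read_polarized_stack(cfg$io$stack, layout = cfg$io$layout)
  g <- if (!is.null(cfg$io$calibration)) run_gfactor(cfg) else cfg$optics$g_factor
  optics <- optics_config(g, cfg$optics$numerical_aperture,
                          cfg$optics$refractive_index)
  prep <- do.call(preprocess_config, cfg$preprocess)
  dir.create(cfg$io$output_dir, showWarnings = FALSE, recursive = TRUE)
  maps <- vector("list", length(stack$frames))
  for (i in seq_along(stack$frames)) {
    maps[[i]] <- tryCatch(
      process_frame(stack$frames[[i]], optics, prep),
      error = function(e) abort(
        sprintf("frame %d: %s", i, conditionMessage(e)),
        "anisokit_degenerate_data_error"))
    if (isTRUE(cfg$io$write_maps))
      write_anisotropy_map(maps[[i]], file.path(
        cfg$io$output_dir, sprintf("anisotropy_%03d.tif", i)))
    message(sprintf("process: frame %d/%d, %d valid px, mean r = %.4f",
                    i, length(stack$frames), maps[[i]]$n_valid,
                    mean_roi(maps[[i]])))
  }
  summary_df <- data.frame(
    frame = seq_along(maps),
    coord = stack$coords,
    axis_kind = stack$axis_kind,
    r_mean = vapply(maps, mean_roi, numeric(1)),
    n_valid = vapply(maps, function(m) m$n_valid, numeric(1)))
  utils::write.csv(summary_df,
                   file.path(cfg$io$output_dir, "frame_summary.csv"),
                   row.names = FALSE)
  write_provenance(cfg, cfg$io$output_dir, "process")
  invisible(summary_df)
}

#' Run the `quantify` pipeline step
#'
#' For a time-axis summary, assembles the assay trace, fits the three
#' phases, and writes `assay_trace.csv` and `assay_metrics.csv`. For a
#' z-axis summary, applies the minimum-pixel slice filter and writes the
#' pooled whole-stack mean to `zstack_mean.csv`.
#'
#' @param cfg Config path or [read_pipeline_config()] result. The frame
#'   summary is read from `io$output_dir/frame_summary.csv` (written by
#'   [run_process()]) unless `io$frame_summary` points elsewhere.
#' @param allow_undefined Return normally even when a metric is undefined
#'   (default TRUE; the command-line wrapper sets FALSE and exits nonzero).
#' @return Invisibly, the metrics ([assay_metrics()]) or pooled-mean list.
#' @export
run_quantify <- function(cfg, allow_undefined = TRUE) {
  cfg <- resolve_cfg(cfg)
  path <- cfg$io$frame_summary %||%
    file.path(cfg$io$output_dir, "frame_summary.csv")
  if (!file.exists(path))
    abort(paste0("frame summary not found: ", path),
          "anisokit_validation_error")
  df <- utils::read.csv(path)
  dir.create(cfg$io$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (identical(df$axis_kind[1], "z")) {
    keep <- df$n_valid >= cfg$assay$min_pixels
    if (!any(keep))
      abort("no slice survives the minimum-pixel filter",
            "anisokit_degenerate_data_error")
    pooled <- sum(df$r_mean[keep] * df$n_valid[keep]) / sum(df$n_valid[keep])
    out <- list(pooled_mean_r = pooled, n_slices_used = sum(keep))
    utils::write.csv(as.data.frame(out),
                     file.path(cfg$io$output_dir, "zstack_mean.csv"),
                     row.names = FALSE)
    message(sprintf("quantify: pooled mean r = %.4f over %d slice(s)",
                    pooled, sum(keep)))
    write_provenance(cfg, cfg$io$output_dir, "quantify")
    return(invisible(out))
  }
  bounds <- as.numeric(cfg$assay$phase_bounds)
  trace <- assay_trace(df$coord, df$r_mean, df$n_valid, phase_bounds = bounds)
  fits <- tryCatch(fit_phases(trace, require_all = FALSE), error = function(e)
    abort(conditionMessage(e), "anisokit_fit_error"))
  metrics <- assay_metrics(trace, fits, use_fits = isTRUE(cfg$assay$use_fits))
  write_trace_csv(trace, file.path(cfg$io$output_dir, "assay_trace.csv"))
  write_metrics_csv(metrics, file.path(cfg$io$output_dir, "assay_metrics.csv"))
  write_provenance(cfg, cfg$io$output_dir, "quantify")
  message(sprintf(paste0(
    "quantify: drop %.4g, depletion t1/2 %.4g s, recovery t1/2 %.4g s, ",
    "baseline change %.4g"),
    metrics$diamide_drop, metrics$depletion_half_life_s,
    metrics$recovery_half_life_s, metrics$baseline_change))
  undef <- is.na(metrics$depletion_half_life_s) ||
    is.na(metrics$recovery_half_life_s)
  if (undef && !allow_undefined)
    abort("an assay metric is undefined (amplitude below the noise floor)",
          "anisokit_degenerate_data_error")
  invisible(metrics)
}

#' Run simulate, process and quantify in sequence
#'
#' The simulated stack feeds straight into processing. Because the
#' simulation knows its own instrument truth, the processing parameters
#' (G factor, NA, refractive index, background) are taken from the
#' `simulate$imaging` section so that the composed run is self-consistent.
#'
#' @param cfg Config path or [read_pipeline_config()] result.
#' @param allow_undefined Passed to [run_quantify()].
#' @return Invisibly, the quantify result.
#' @export
run_all <- function(cfg, allow_undefined = TRUE) {
  cfg <- resolve_cfg(cfg)
  if (is.null(cfg$simulate))
    abort("config has no `simulate` section", "anisokit_validation_error")
  paths <- run_simulate(cfg)
  img <- do.call(imaging_params, cfg$simulate$imaging %||% list())
  cfg$optics$g_factor <- img$g_factor_true
  cfg$optics$numerical_aperture <- img$numerical_aperture
  cfg$optics$refractive_index <- img$refractive_index
  cfg$preprocess$background <- img$background_counts
  cfg$io$stack <- paths$stack
  run_process(cfg)
  run_quantify(cfg, allow_undefined = allow_undefined)
}
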