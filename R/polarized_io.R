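# Stack storage: one multi-page grayscale TIFF with channel pairs interleaved
# (page 2i-1 = parallel, page 2i = perpendicular of frame i) plus a YAML
# sidecar (<path>.yaml) carrying axis kind, spacing, coordinates, pixel size
# and the sample format. Acquired data are 16-bit unsigned and round-trip
# bit-exactly; simulated float data are stored as 32-bit float after scaling
# into [0, 1] by a per-stack factor recorded in the sidecar, so they
# round-trip to single precision.

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a polarized stack to a multi-page TIFF plus YAML sidecar
#'
#' Pages are interleaved parallel/perpendicular. Integer-valued stacks (all
#' intensities whole numbers in \[0, 65535\]) are stored as 16-bit unsigned
#' and are recovered bit-exactly by [read_polarized_stack()]; other stacks
#' are stored as 32-bit float (single precision).
#'
#' @param stack A [polarized_stack()].
#' @param path Output TIFF path; the sidecar is written to `paste0(path, ".yaml")`.
#' @return `path`, invisibly.
#' @export
write_polarized_stack <- function(stack, path) {
  if (!inherits(stack, "polarized_stack")) stop("`stack` must be a polarized_stack")
  if (!length(stack$frames)) stop("cannot write an empty stack")
  pages <- vector("list", 2L * length(stack$frames))
  for (i in seq_along(stack$frames)) {
    pages[[2L * i - 1L]] <- stack$frames[[i]]$parallel
    pages[[2L * i]] <- stack$frames[[i]]$perpendicular
  }
  vals <- unlist(pages, use.names = FALSE)
  if (any(vals < 0)) stop("cannot store negative intensities")
  integral <- all(vals == floor(vals)) && max(vals) <= 65535
  if (integral) {
    fmt <- "uint16"; scale <- 65535
    pages <- lapply(pages, function(p) p / 65535)
    bits <- 16L
  } else {
    fmt <- "float32"; scale <- max(max(vals), 1)
    pages <- lapply(pages, function(p) p / scale)
    bits <- 32L
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits)
  if (!isTRUE(ok > 0)) stop("failed to write TIFF: ", path)
  meta <- list(
    format_version = 1L,
    axis_kind = stack$axis_kind,
    spacing = stack$spacing,
    coords = as.numeric(stack$coords),
    pixel_size_um = stack$frames[[1]]$pixel_size_um,
    sample_format = fmt,
    scale = scale,
    page_layout = "interleaved_parallel_perpendicular")
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a polarized stack from a multi-page TIFF
#'
#' Metadata are taken from the YAML sidecar written by
#' [write_polarized_stack()] when present; otherwise `layout` must supply
#' them. Missing per-frame coordinates are synthesized as
#' `(index - 1) * spacing`, never inferred from filenames.
#'
#' @param path TIFF path.
#' @param layout Optional list of layout defaults used when no sidecar
#'   exists: `axis_kind` (`"z"` or `"time"`), `spacing`, `pixel_size_um`,
#'   and `channel_order` (`"parallel_first"`, the default, or
#'   `"perpendicular_first"`).
#' @return A [polarized_stack()].
#' @export
read_polarized_stack <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- NULL
  if (file.exists(sidecar_path(path))) meta <- yaml::read_yaml(sidecar_path(path))
  if (is.null(meta)) {
    if (is.null(layout)) stop("no sidecar found for ", path,
                              "; a `layout` descriptor is required")
    meta <- list(axis_kind = layout$axis_kind %||% "z",
                 spacing = layout$spacing %||% 1,
                 coords = NULL,
                 pixel_size_um = layout$pixel_size_um %||% 1,
                 sample_format = layout$sample_format %||% "uint16",
                 scale = layout$scale %||%
                   if (identical(layout$sample_format, "float32")) 1 else 65535)
  }
  perp_first <- identical((layout$channel_order %||% "parallel_first"),
                          "perpendicular_first")

  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% 2L != 0L)
    stop("page count (", length(pages), ") is not divisible into channel pairs")
  dims <- lapply(pages, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("shape mismatch between channel pages")
  # readTIFF normalizes to [0, 1]; undo using the recorded sample format
  pages <- if (identical(meta$sample_format, "uint16")) {
    lapply(pages, function(p) round(p * 65535))
  } else {
    lapply(pages, function(p) p * meta$scale)
  }

  n <- length(pages) %/% 2L
  coords <- if (!is.null(meta$coords)) as.numeric(meta$coords)
            else (seq_len(n) - 1) * meta$spacing
  if (length(coords) != n) stop("sidecar coordinate count does not match frame count")
  frames <- lapply(seq_len(n), function(i) {
    a <- pages[[2L * i - 1L]]; b <- pages[[2L * i]]
    if (perp_first) { tmp <- a; a <- b; b <- tmp }
    polarized_frame(
      parallel = a, perpendicular = b,
      depth_um = if (meta$axis_kind == "z") coords[i] else NULL,
      time_s = if (meta$axis_kind == "time") coords[i] else NULL,
      pixel_size_um = meta$pixel_size_um)
  })
  polarized_stack(frames, axis_kind = meta$axis_kind, spacing = meta$spacing)
}

#' Export an anisotropy map as float TIFF plus mask TIFF
#'
#' Writes `r` (with non-mask pixels as 0) as a 32-bit float image scaled
#' into \[0, 1\] (anisotropy is algebraically within \[-0.5, 1\]; values are
#' stored as `(r + 0.5) / 1.5`) and the validity mask as a binary image at
#' `paste0(path, ".mask.tif")`.
#'
#' @param map An [anisotropy_map].
#' @param path Output TIFF path for the anisotropy image.
#' @return `path`, invisibly.
#' @export
write_anisotropy_map <- function(map, path) {
  stopifnot(inherits(map, "anisotropy_map"))
  r <- map$r
  r[!map$mask] <- 0
  tiff::writeTIFF((r + 0.5) / 1.5, path, bits.per.sample = 32L)
  tiff::writeTIFF(map$mask * 1, paste0(path, ".mask.tif"), bits.per.sample = 8L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
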