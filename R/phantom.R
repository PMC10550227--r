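# RNG hygiene: simulator entry points take an explicit seed and restore
# the caller's RNG state, so fixed-seed outputs are bit-reproducible and
# independent of surrounding code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Islet-like expression phantom
#'
#' Builds an elliptical "islet" support filled with Voronoi-style cell
#' territories (nearest of `n_cells` seed points) and draws one lognormal
#' expression level per cell, emulating cell-to-cell variation of sensor
#' expression in a tissue slice. Expression is zero outside the support.
#'
#' @param shape Image dimensions `c(rows, cols)` (default `c(128, 128)`,
#'   an islet slice roughly filling a 40x field of view).
#' @param n_cells Number of cells (>= 1); with a single cell the support
#'   is uniform.
#' @param seed RNG seed; the same seed reproduces the phantom bit-exactly.
#' @param meanlog,sdlog Lognormal parameters of per-cell expression
#'   (defaults 0 and 0.4).
#' @param semiaxes Ellipse semi-axes as fractions of the image half-sides
#'   (default `c(0.9, 0.8)`).
#' @return An object of class `phantom`: `expression` matrix,
#'   `cell_labels` integer matrix (0 outside the support), `support`
#'   logical matrix.
#' @export
make_phantom <- function(shape = c(128, 128), n_cells = 40, seed = 1,
                         meanlog = 0, sdlog = 0.4,
                         semiaxes = c(0.9, 0.8)) {
  if (length(shape) != 2L || any(shape < 4)) stop("degenerate phantom shape")
  if (n_cells < 1) stop("n_cells must be >= 1")
  with_seed(seed, {
    rows <- shape[1]; cols <- shape[2]
    cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
    ay <- semiaxes[1] * rows / 2; ax <- semiaxes[2] * cols / 2
    yy <- matrix(seq_len(rows), rows, cols)
    xx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    support <- ((yy - cy) / ay)^2 + ((xx - cx) / ax)^2 <= 1

    labels <- matrix(0L, rows, cols)
    if (n_cells == 1L) {
      labels[support] <- 1L
    } else {
      idx <- which(support)
      centers <- idx[sample.int(length(idx), min(n_cells, length(idx)))]
      cyx <- cbind((centers - 1) %% rows + 1, (centers - 1) %/% rows + 1)
      d2 <- outer(yy[idx], cyx[, 1], "-")^2 + outer(xx[idx], cyx[, 2], "-")^2
      labels[idx] <- max.col(-d2, ties.method = "first")
    }
    expr_per_cell <- stats::rlnorm(max(labels), meanlog = meanlog, sdlog = sdlog)
    expression <- matrix(0, rows, cols)
    expression[support] <- expr_per_cell[labels[support]]
    structure(list(expression = expression, cell_labels = labels,
                   support = support, seed = seed,
                   meanlog = meanlog, sdlog = sdlog),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, %d cells, %d support px\n",
              nrow(x$expression), ncol(x$expression),
              max(x$cell_labels), sum(x$support)))
  invisible(x)
}
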