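#' Block-average an image to an N x N amplitude grid
#'
#' Partitions the image into an `N x N` grid of near-equal tiles (floor/ceil
#' split when a side is not divisible by `N`) and takes the mean gray value
#' of each tile as the central luminance of its phosphene.
#'
#' @param image Grayscale matrix in `[0, 255]`, both sides `>= resolution`.
#' @param resolution Grid size `N`.
#' @return Object of class `"phosphene_grid"`: `amplitudes` (N x N),
#'   `resolution`, `pitch` (field size / N, pixels), `centers_row`/
#'   `centers_col` (pixel indices of tile centers, snapped to the grid).
#' @export
block_amplitudes <- function(image, resolution) {
  H <- nrow(image); W <- ncol(image)
  N <- as.integer(resolution)
  if (N < 1L || N > min(H, W))
    stop("resolution must lie between 1 and the smaller image side")
  row_tile <- floor((seq_len(H) - 1L) * N / H) + 1L
  col_tile <- floor((seq_len(W) - 1L) * N / W) + 1L
  tile_id <- outer(row_tile, (col_tile - 1L) * N, `+`)
  sums <- rowsum(c(image), c(tile_id))
  cnts <- tabulate(c(tile_id), nbins = N * N)
  A <- matrix(sums / cnts, N, N)
  ctr <- function(tiles, n) {
    b <- vapply(seq_len(n), function(k) range(which(tiles == k)),
                numeric(2))
    as.integer(floor((b[1, ] + b[2, ]) / 2))
  }
  structure(list(amplitudes = A, resolution = N,
                 pitch = min(H, W) / N, field = c(H, W),
                 centers_row = ctr(row_tile, N), centers_col = ctr(col_tile, N)),
            class = "phosphene_grid")
}

#' @export
print.phosphene_grid <- function(x, ...) {
  cat(sprintf("phosphene grid %d x %d, pitch %.2f px, amplitudes in [%.1f, %.1f]\n",
              x$resolution, x$resolution, x$pitch,
              min(x$amplitudes), max(x$amplitudes)))
  invisible(x)
}

#' Render a phosphene grid as a Gaussian-dot percept
#'
#' Each phosphene is a radially symmetric Gaussian centered on its tile
#' center and truncated at `3 * sigma`. By default the Gaussian is
#' peak-normalized (peak luminance equals the tile amplitude), so a
#' constant image renders as a constant-brightness dot array regardless of
#' `sigma`; the density-normalized form (`1/(2*pi*sigma^2)` prefactor) is
#' available for completeness. Overlapping phosphenes combine by pointwise
#' maximum and the raster is clipped to `[0, 255]`.
#'
#' @param grid A `"phosphene_grid"`.
#' @param field_size `(H, W)` of the output raster; defaults to the grid's
#'   source field.
#' @param sigma Gaussian spread in pixels (default `pitch / 6`, visually
#'   separated dots).
#' @param normalize `"peak"` (default) or `"density"`.
#' @return Object of class `"phosphene_percept"`: `raster` in `[0, 255]`
#'   plus the `grid` and `sigma` that produced it.
#' @export
render_phosphenes <- function(grid, field_size = grid$field, sigma = NULL,
                              normalize = c("peak", "density")) {
  normalize <- match.arg(normalize)
  if (is.null(sigma)) sigma <- grid$pitch / 6
  if (sigma <= 0) stop("sigma must be positive")
  H <- field_size[1]; W <- field_size[2]
  N <- grid$resolution
  out <- matrix(0, H, W)
  rad <- ceiling(3 * sigma)
  pref <- if (normalize == "peak") 1 else 1 / (2 * pi * sigma^2)
  for (i in seq_len(N)) {
    cr <- grid$centers_row[i]
    rr <- max(1L, cr - rad):min(H, cr + rad)
    dr2 <- (rr - cr)^2
    for (j in seq_len(N)) {
      A <- grid$amplitudes[i, j]
      if (A == 0) next
      ccol <- grid$centers_col[j]
      cc <- max(1L, ccol - rad):min(W, ccol + rad)
      d2 <- outer(dr2, (cc - ccol)^2, `+`)
      g <- pref * A * exp(-d2 / (2 * sigma^2))
      g[d2 > (3 * sigma)^2] <- 0
      out[rr, cc] <- pmax(out[rr, cc], g)
    }
  }
  structure(list(raster = clip255(out), grid = grid, sigma = sigma),
            class = "phosphene_percept")
}

#' Lowering Resolution with Gaussian dots (LRG)
#'
#' Composition of [block_amplitudes()] and [render_phosphenes()]: the
#' simulated percept an implant with an `N x N` electrode array would
#' deliver for the given image.
#'
#' @inheritParams block_amplitudes
#' @param sigma_ratio Gaussian spread as a fraction of the dot pitch
#'   (default 1/6; at or below 1/6 the dots do not overlap).
#' @param normalize Passed to [render_phosphenes()].
#' @return A `"phosphene_percept"`.
#' @export
lrg <- function(image, resolution, sigma_ratio = 1 / 6,
                normalize = c("peak", "density")) {
  grid <- block_amplitudes(image, resolution)
  render_phosphenes(grid, sigma = sigma_ratio * grid$pitch,
                    normalize = match.arg(normalize))
}

#' Render one percept per electrode-array resolution
#'
#' @inheritParams lrg
#' @param resolutions Integer vector of grid sizes; the default covers the
#'   six standard simulated-prosthesis resolutions.
#' @return Named list of `"phosphene_percept"`s, one per resolution.
#' @export
lrg_batch <- function(image, resolutions = c(8L, 16L, 24L, 32L, 48L, 64L),
                      sigma_ratio = 1 / 6) {
  out <- lapply(resolutions, function(N) lrg(image, N, sigma_ratio))
  names(out) <- as.character(resolutions)
  out
}
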