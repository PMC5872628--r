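#' SLIC superpixel segmentation
#'
#' Clusters an image into compact, spatially connected superpixels with the
#' SLIC algorithm (k-means in a joint CIELAB + position space, with a
#' spatial normalization by the expected grid step). Superpixels are the
#' node unit of the saliency graph.
#'
#' @param image Grayscale matrix or RGB array in `[0, 255]`.
#' @param n_target Requested number of superpixels (>= 4). The achieved
#'   count `n` may differ slightly after grid seeding and connectivity
#'   enforcement.
#' @param compactness SLIC compactness weight `m` (native CIELAB scale;
#'   10 is the conventional default).
#' @param seed Integer seed, part of the determinism contract. SLIC itself
#'   is deterministic; the seed is recorded so downstream manifests can
#'   reproduce runs.
#' @param max_iter Number of assignment/update sweeps.
#' @return An object of class `"superpixels"`: list with `labels` (integer
#'   matrix, contiguous labels `0..n-1`), `n`, `mean_color` (n x 3 CIELAB,
#'   channels scaled to `[0, 1]`), `centroid` (n x 2, row/col in pixels,
#'   1-based), and boundary flags `is_boundary_top/bottom/left/right`.
#' @export
compute_superpixels <- function(image, n_target = 200, compactness = 10,
                                seed = 0L, max_iter = 10L) {
  d <- dim(image)
  if (is.null(d) || d[1] < 2L || d[2] < 2L) stop("image must be at least 2x2")
  if (n_target < 4L) stop("n_target must be >= 4")
  H <- d[1]; W <- d[2]
  lab <- rgb_to_lab(image)
  labels <- .slic_cpp(lab, H, W, as.integer(n_target), compactness,
                      as.integer(max_iter))
  n <- max(labels) + 1L
  idx <- as.integer(labels) + 1L           # 1-based superpixel id per pixel
  cnt <- tabulate(idx, nbins = n)
  # mean color in [0,1]-scaled Lab: L/100, (a+110)/220, (b+110)/220
  lab01 <- cbind(lab[, 1] / 100, (lab[, 2] + 110) / 220, (lab[, 3] + 110) / 220)
  mean_color <- rowsum(lab01, idx) / cnt
  rc <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  centroid <- rowsum(rc, idx) / cnt
  side <- function(v) {
    f <- logical(n); f[unique(v) + 1L] <- TRUE; f
  }
  structure(list(
    labels = labels, n = n, mean_color = unname(mean_color),
    centroid = unname(centroid), area = cnt, seed = as.integer(seed),
    is_boundary_top = side(labels[1, ]),
    is_boundary_bottom = side(labels[H, ]),
    is_boundary_left = side(labels[, 1]),
    is_boundary_right = side(labels[, W])
  ), class = "superpixels")
}

#' @export
print.superpixels <- function(x, ...) {
  cat(sprintf("SLIC superpixels: n = %d over a %d x %d raster\n",
              x$n, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' @param mask Binary matrix (0/1).
#' @param connectivity 4 or 8.
#' @return Integer matrix; 0 is background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  storage.mode(mask) <- "integer"
  .label_components_cpp(mask, as.integer(connectivity))
}
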