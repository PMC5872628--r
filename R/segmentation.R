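#' Adaptive dual thresholds for a saliency map
#'
#' The high threshold is the Otsu threshold of the saliency histogram
#' (exhaustive between-class-variance search over 256 bins); the low
#' threshold is half of it. Strong pixels seed the object, weak pixels fill
#' it in through connectivity.
#'
#' @param saliency Numeric raster with values in `[0, 1]`.
#' @return List of class `"threshold_pair"` with `t_low` and `t_high`.
#' @export
select_thresholds <- function(saliency) {
  if (any(saliency < 0 | saliency > 1)) stop("saliency values must lie in [0,1]")
  if (diff(range(saliency)) == 0)
    stop("degenerate saliency map: constant values admit no threshold")
  t_high <- otsu_threshold(saliency)
  structure(list(t_low = t_high / 2, t_high = t_high),
            class = "threshold_pair")
}

# Otsu's method: exhaustive search over 256 equal bins on [0,1] for the
# cut maximizing between-class variance; returns the upper edge of the
# best cut bin (pixels >= threshold fall in the upper class).
otsu_threshold <- function(x, levels = 256L) {
  h <- tabulate(pmin(floor(x * levels), levels - 1L) + 1L, nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  # between-class variance for cut after bin k (k = 1..levels-1)
  k <- seq_len(levels - 1L)
  denom <- w0[k] * (1 - w0[k])
  bcv <- ifelse(denom > 0, (mu_t * w0[k] - mu0[k])^2 / denom, 0)
  best <- which.max(bcv)
  best / levels
}

#' Hysteresis (dual-threshold) segmentation
#'
#' Pixels at or above `t_high` are kept outright; pixels in the weak band
#' `[t_low, t_high)` are kept only when their connected component over the
#' `>= t_low` support contains at least one strong pixel.
#'
#' @param saliency Numeric raster in `[0, 1]`.
#' @param t A `"threshold_pair"` (or list with `t_low`, `t_high`).
#' @param connectivity 4 or 8 (default 8).
#' @return Binary matrix mask (0/1).
#' @export
hysteresis_segment <- function(saliency, t, connectivity = 8L) {
  if (t$t_low > t$t_high || t$t_low < 0 || t$t_high > 1)
    stop("invalid threshold pair")
  weak <- saliency >= t$t_low
  strong <- saliency >= t$t_high
  if (!any(weak)) return(matrix(0, nrow(saliency), ncol(saliency)))
  lab <- label_components(weak * 1L, connectivity)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  (lab %in% keep) * matrix(1, nrow(saliency), ncol(saliency))
}

#' Morphological cleanup of a binary mask
#'
#' Opening then closing with a square structuring element removes isolated
#' pixels and seals pinholes; connected components smaller than a fraction
#' of the image area are then dropped.
#'
#' @param mask Binary matrix (0/1).
#' @param min_area_frac Minimum component area as a fraction of total pixels
#'   (default 0.001); components below `min_area_frac * H * W` are removed.
#' @param struct_size Odd side length of the square structuring element
#'   (default 3).
#' @param largest_only Keep only the largest surviving component (for scenes
#'   assumed to contain a single main object); default `FALSE`.
#' @param connectivity 4 or 8 for the component analysis.
#' @return Binary matrix mask.
#' @export
clean_mask <- function(mask, min_area_frac = 0.001, struct_size = 3L,
                       largest_only = FALSE, connectivity = 8L) {
  if (struct_size %% 2L == 0L) stop("struct_size must be odd")
  if (min_area_frac < 0 || min_area_frac >= 1)
    stop("min_area_frac must lie in [0, 1)")
  stopifnot_binary(mask)
  kern <- EBImage::makeBrush(struct_size, shape = "box")
  m <- EBImage::imageData(EBImage::closing(EBImage::opening(mask, kern), kern))
  m <- (m > 0) * 1
  lab <- label_components(m, connectivity)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    cutoff <- min_area_frac * length(mask)
    keep <- which(areas >= cutoff)
    if (largest_only && length(keep) > 1L)
      keep <- keep[which.max(areas[keep])]
    m <- (lab %in% keep) * 1
    dim(m) <- dim(mask)
  }
  m
}

#' Saliency map to object mask
#'
#' Full segmentation stage: adaptive dual thresholds, hysteresis, and
#' morphological cleanup.
#'
#' @param saliency Pixel-level saliency raster in `[0, 1]`.
#' @inheritParams hysteresis_segment
#' @inheritParams clean_mask
#' @return List with the binary `mask` and the `thresholds` used.
#' @export
segment_saliency <- function(saliency, connectivity = 8L,
                             min_area_frac = 0.001, struct_size = 3L,
                             largest_only = FALSE) {
  t <- select_thresholds(saliency)
  raw <- hysteresis_segment(saliency, t, connectivity)
  mask <- clean_mask(raw, min_area_frac = min_area_frac,
                     struct_size = struct_size, largest_only = largest_only,
                     connectivity = connectivity)
  list(mask = mask, thresholds = t)
}
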