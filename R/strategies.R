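#' Split an image into foreground and background layers
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param mask Binary object mask of the same shape.
#' @return List with `f_F` (foreground pixels, 0 elsewhere), `f_B`
#'   (background pixels, 0 elsewhere) and `mask`; the two supports are
#'   disjoint and together cover the image.
#' @export
split_foreground_background <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) stop("image/mask shape mismatch")
  stopifnot_binary(mask)
  list(f_F = image * mask, f_B = image * (1 - mask), mask = mask)
}

#' FEBR: foreground edge detection with background reduction
#'
#' Inside the object mask the output is the binarized multiscale edge map
#' of the foreground (edge pixels 255, other foreground 0), sharpening the
#' object's contour; outside the mask gray values are halved
#' (`floor(v / 2)`, range 0..127) so residual background context survives
#' at reduced contrast. The two layers are fused by a pixelwise sum over
#' their disjoint supports.
#'
#' @inheritParams split_foreground_background
#' @param scales Sobel kernel sizes for the multiscale edge detector.
#' @param threshold `"otsu"` or a fixed numeric magnitude threshold.
#' @return Grayscale matrix in `[0, 255]`.
#' @export
febr <- function(image, mask, scales = c(3L, 7L), threshold = "otsu") {
  if (!identical(dim(image), dim(mask))) stop("image/mask shape mismatch")
  stopifnot_binary(mask)
  g_B <- floor(image / 2) * (1 - mask)
  if (!any(mask == 1)) {
    warning("empty foreground mask; returning the halved image")
    return(floor(image / 2))
  }
  fg <- image * mask
  edges <- multiscale_edges(fg, scales = scales, threshold = threshold)
  g_F <- 255 * edges * mask
  g_F + g_B
}

#' Minimal zoom window around the foreground
#'
#' @param mask Nonempty binary mask.
#' @param pad_frac Fractional padding added on each side of the tight
#'   bounding box (of its height/width), clipped to the image bounds.
#' @return List of class `"zoom_window"` with 1-based inclusive `top`,
#'   `left`, `bottom`, `right`.
#' @export
zoom_window <- function(mask, pad_frac = 0) {
  stopifnot_binary(mask)
  if (pad_frac < 0) stop("pad_frac must be >= 0")
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("degenerate input: empty mask has no zoom window")
  top <- min(idx[, 1]); bottom <- max(idx[, 1])
  left <- min(idx[, 2]); right <- max(idx[, 2])
  ph <- round(pad_frac * (bottom - top + 1))
  pw <- round(pad_frac * (right - left + 1))
  structure(list(top = max(1L, top - ph),
                 left = max(1L, left - pw),
                 bottom = min(nrow(mask), bottom + ph),
                 right = min(ncol(mask), right + pw)),
            class = "zoom_window")
}

# aspect-preserving resize into (H, W), zero letterbox; bilinear for
# images, nearest-neighbor for masks
resize_letterbox <- function(m, H, W, nearest = FALSE) {
  h <- nrow(m); w <- ncol(m)
  s <- min(H / h, W / w)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  rs <- EBImage::resize(t(m), w = nh, h = nw,
                        filter = if (nearest) "none" else "bilinear")
  rs <- t(EBImage::imageData(rs))
  out <- matrix(0, H, W)
  r0 <- (H - nh) %/% 2L; c0 <- (W - nw) %/% 2L
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- rs
  out
}

#' FZE: foreground zoom with edge detection
#'
#' Crops the image and mask to the minimal box around the foreground,
#' scales it (aspect-preserving, zero letterbox) to the presentation field
#' so the object fills the visual field, removes the background entirely,
#' and edge-detects the zoomed foreground. Output is binary-valued
#' `{0, 255}`.
#'
#' @inheritParams febr
#' @param field_size `(H, W)` of the presented image; default the input
#'   shape.
#' @param pad_frac Padding fraction for [zoom_window()].
#' @return Grayscale matrix with values in `{0, 255}`.
#' @export
fze <- function(image, mask, field_size = dim(image), pad_frac = 0.05,
                scales = c(3L, 7L), threshold = "otsu") {
  if (!identical(dim(image), dim(mask))) stop("image/mask shape mismatch")
  stopifnot_binary(mask)
  if (!any(mask == 1)) stop("degenerate input: empty mask cannot be zoomed")
  zw <- zoom_window(mask, pad_frac)
  rows <- zw$top:zw$bottom; cols <- zw$left:zw$right
  H <- field_size[1]; W <- field_size[2]
  zi <- resize_letterbox(image[rows, cols, drop = FALSE], H, W)
  zm <- resize_letterbox(mask[rows, cols, drop = FALSE], H, W, nearest = TRUE)
  zm <- (zm > 0.5) * 1
  fg <- zi * zm
  edges <- multiscale_edges(fg, scales = scales, threshold = threshold)
  255 * edges * zm
}
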