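#' Sobel gradient at a single scale
#'
#' Convolves the image with separable Sobel derivative kernels. The 3x3
#' kernel is the classic `[1,2,1]' x [-1,0,1]`; the 7x7 kernel is built the
#' same way from binomial vectors: smoothing `[1,6,15,20,15,6,1]` and
#' derivative `conv([-1,0,1], [1,4,6,4,1]) = [-1,-4,-5,0,5,4,1]`, so the
#' large scale is the small one with extra binomial presmoothing. Borders
#' are mirrored (reflect-101).
#'
#' @param image Grayscale matrix (any real scale).
#' @param kernel_size 3 or 7.
#' @return List of class `"gradient_field"` with `Gx` (horizontal
#'   derivative, x = column), `Gy` (vertical), `magnitude`
#'   (`sqrt(Gx^2+Gy^2)`), `direction` (radians), and `kernel_size`.
#' @param direction_convention `"atan2_gy_gx"` (default, the conventional
#'   `atan2(Gy, Gx)`) or `"atan_gx_gy"` (the transposed variant
#'   `atan2(Gx, Gy)`).
#' @export
sobel_gradient <- function(image, kernel_size = 3L,
                           direction_convention = c("atan2_gy_gx",
                                                    "atan_gx_gy")) {
  if (length(dim(image)) != 2L) stop("sobel_gradient expects a grayscale matrix")
  direction_convention <- match.arg(direction_convention)
  k <- sobel_vectors(kernel_size)
  Gx <- conv_separable(image, row_k = k$smooth, col_k = k$deriv)
  Gy <- conv_separable(image, row_k = k$deriv, col_k = k$smooth)
  mag <- sqrt(Gx^2 + Gy^2)
  dir <- if (direction_convention == "atan2_gy_gx") atan2(Gy, Gx)
         else atan2(Gx, Gy)
  structure(list(Gx = Gx, Gy = Gy, magnitude = mag, direction = dir,
                 kernel_size = as.integer(kernel_size)),
            class = "gradient_field")
}

sobel_vectors <- function(kernel_size) {
  if (kernel_size == 3L) {
    list(smooth = c(1, 2, 1), deriv = c(-1, 0, 1))
  } else if (kernel_size == 7L) {
    list(smooth = choose(6, 0:6),                       # 1 6 15 20 15 6 1
         deriv = c(-1, -4, -5, 0, 5, 4, 1))             # [-1,0,1] * binom(4)
  } else {
    stop("kernel_size must be 3 or 7")
  }
}

# reflect-101 padding: mirror without repeating the edge sample
pad_reflect101 <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(rev(seq_len(r) + 1L), seq_len(H), H - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(W), W - seq_len(r))
  m[ri, ci, drop = FALSE]
}

# separable cross-correlation: row_k applied down columns (vertical),
# col_k applied along rows (horizontal); reflect-101 borders
conv_separable <- function(m, row_k, col_k) {
  r <- (length(row_k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  p <- pad_reflect101(m, r)
  tmp <- matrix(0, H, W + 2L * r)
  for (i in seq_along(row_k))
    if (row_k[i] != 0)
      tmp <- tmp + row_k[i] * p[(i - 1L) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(col_k))
    if (col_k[j] != 0)
      out <- out + col_k[j] * tmp[, (j - 1L) + seq_len(W), drop = FALSE]
  out
}

#' Fuse gradient magnitudes across scales by geometric mean
#'
#' The fused edge strength is the pointwise geometric mean of the per-scale
#' magnitudes: spurious responses present at only one scale are suppressed.
#'
#' @param fields List of `"gradient_field"`s (or bare magnitude matrices)
#'   of identical shape.
#' @return Numeric matrix of fused magnitudes.
#' @export
multiscale_magnitude <- function(fields) {
  mags <- lapply(fields, function(f)
    if (inherits(f, "gradient_field")) f$magnitude else f)
  if (length(mags) < 1L) stop("need at least one gradient field")
  d <- dim(mags[[1]])
  if (!all(vapply(mags, function(m) identical(dim(m), d), logical(1))))
    stop("gradient fields must share a common shape")
  prod <- Reduce(`*`, mags)
  prod^(1 / length(mags))
}

#' Threshold an edge-magnitude raster to a binary edge mask
#'
#' @param magnitude Nonnegative magnitude raster.
#' @param method `"otsu"` (adaptive, default) or `"fixed"`.
#' @param value Threshold for `method = "fixed"`, on the magnitude scale.
#' @return Binary matrix: 1 where magnitude exceeds the threshold.
#' @export
threshold_edges <- function(magnitude, method = c("otsu", "fixed"),
                            value = NULL) {
  method <- match.arg(method)
  if (any(magnitude < 0)) stop("magnitude must be nonnegative")
  if (method == "fixed") {
    if (is.null(value)) stop("fixed thresholding requires a value")
    return((magnitude > value) * 1)
  }
  mx <- max(magnitude)
  if (mx == 0) return(magnitude * 0)
  (magnitude / mx >= otsu_threshold(magnitude / mx)) * 1
}

#' Multiscale Sobel edge mask
#'
#' Convenience wrapper: per-scale Sobel gradients, geometric-mean fusion,
#' and binarization.
#'
#' @param image Grayscale matrix.
#' @param scales Integer vector of Sobel kernel sizes (default `c(3, 7)`).
#' @param threshold `"otsu"` or a fixed numeric threshold on the fused
#'   magnitude.
#' @return Binary matrix edge mask.
#' @export
multiscale_edges <- function(image, scales = c(3L, 7L), threshold = "otsu") {
  fields <- lapply(scales, function(s) sobel_gradient(image, s))
  fused <- multiscale_magnitude(fields)
  if (identical(threshold, "otsu")) threshold_edges(fused, "otsu")
  else threshold_edges(fused, "fixed", value = as.numeric(threshold))
}
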