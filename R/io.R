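#' Read an image as an 8-bit raster
#'
#' Reads PNG, JPEG or PGM files into the package's raster convention: a
#' numeric matrix (grayscale) or H x W x 3 array (RGB) with values in
#' 0..255, row-major, origin at the top-left.
#'
#' @param path Path to a PNG, JPEG (.jpg/.jpeg) or PGM (P2/P5) file.
#' @return Numeric matrix or 3-channel array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    x <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores images x,y (transposed relative to row/col)
    x <- if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
  } else if (ext == "pgm") {
    return(read_pgm(path))
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1L]
  x * 255
}

# Minimal PGM (P2 ascii / P5 binary) reader; maxval <= 255 supported.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # read header tokens, skipping comments
  buf <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || !nzchar(ch)) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!nzchar(ch) || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (maxval > 255L) stop("16-bit PGM not supported")
  n <- w * h
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", n = n))
  } else if (magic == "P2") {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else stop("not a PGM file: ", path)
  matrix(v, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval)
}

#' Write an 8-bit raster as PNG
#'
#' @param x Numeric matrix or 3-channel array with values in `[0, 255]`;
#'   values are clipped and rounded.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  x <- round(pmin(pmax(x, 0), 255)) / 255
  png::writePNG(x, target = path)
  invisible(path)
}

#' Convert a color or grayscale raster to grayscale (Rec. 601 luma)
#'
#' @param image Matrix or H x W x 3 array in `[0, 255]`.
#' @return Numeric matrix in `[0, 255]`.
#' @export
to_gray <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# sRGB (0..255) raster -> CIELAB, returned as (H*W) x 3 matrix in
# column-major pixel order, native Lab scale (L in 0..100).
rgb_to_lab <- function(image) {
  if (length(dim(image)) == 2L) {
    rgb <- cbind(c(image), c(image), c(image)) / 255
  } else {
    rgb <- cbind(c(image[, , 1]), c(image[, , 2]), c(image[, , 3])) / 255
  }
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

# clip helper used across modules
clip255 <- function(x) pmin(pmax(x, 0), 255)

stopifnot_binary <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be strictly binary {0,1}")
}
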