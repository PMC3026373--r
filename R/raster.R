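#' Construct a raster image
#'
#' A raster image is an `H x W x 3` integer array of 8-bit RGB values with a
#' top-left origin: the first index is the row (y), the second the column (x).
#'
#' @param pixels Numeric array of dimension `H x W x 3` (or an `H x W` matrix,
#'   replicated across the three channels), values in `[0, 255]`.
#' @return An integer array of class `raster_image`.
#' @export
raster_image <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array or an H x W matrix")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  px <- array(as.integer(round(pixels)), dim = dim(pixels))
  class(px) <- c("raster_image", class(px))
  px
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %d x %d, 3 channels, range [%d, %d]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Construct a binary mask
#'
#' @param values Logical (or 0/1 numeric) `H x W` matrix; `TRUE` marks positive
#'   (lesion) pixels.
#' @return A logical matrix of class `binary_mask`.
#' @export
binary_mask <- function(values) {
  if (!is.matrix(values)) stop("values must be a matrix")
  v <- matrix(as.logical(values), nrow(values), ncol(values))
  if (anyNA(v)) stop("mask values must be TRUE/FALSE")
  class(v) <- c("binary_mask", class(v))
  v
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d positive>\n", nrow(x), ncol(x), mask_area(x)))
  invisible(x)
}

#' Number of positive pixels in a mask
#'
#' The `Area()` of a binary image: the count of positive pixels.
#'
#' @param mask A [binary_mask()].
#' @return Integer count.
#' @export
mask_area <- function(mask) sum(mask)

# read a raster file into an H x W (x channels) double array in [0, 1]
read_raster_array <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG, JPEG and TIFF are supported): ", path)
  )
  if (length(arr) == 0L) stop("zero-size image: ", path)
  arr
}

#' Read an RGB raster image
#'
#' Reads PNG, JPEG or TIFF files. Grayscale sources are replicated across the
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to the image file.
#' @return A [raster_image()].
#' @export
load_image <- function(path) {
  arr <- read_raster_array(path)
  if (is.matrix(arr)) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] == 1L) arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  if (dim(arr)[3] >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  raster_image(arr * 255)
}

#' Read a binary mask from a raster file
#'
#' A pixel is positive iff its first-channel 8-bit value exceeds 127.
#'
#' @param path Path to a single-channel or RGB raster file.
#' @return A [binary_mask()].
#' @export
load_mask <- function(path) {
  arr <- read_raster_array(path)
  if (!is.matrix(arr)) arr <- arr[, , 1L]
  binary_mask(round(arr * 255) > 127)
}

#' Write a binary mask as a PNG
#'
#' Positive pixels are written as 255, negative as 0, so that
#' `load_mask(save_mask(m))` reproduces `m` exactly.
#'
#' @param mask A [binary_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write an RGB raster image as a PNG
#'
#' @param image A [raster_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

# boundary pixels of a mask: positive pixels with a negative (or out-of-image)
# 4-neighbor; the erosion-difference contour
mask_contour <- function(mask) {
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  binary_mask(m & !interior)
}

#' Render masks over an image
#'
#' Draws each layer's contour or filled region in its color, later layers over
#' earlier ones, as in the usual manual-red / DBSCAN-blue / FCM-green overlay
#' figures.
#'
#' @param image A [raster_image()].
#' @param layers List of layers, each a list with elements `mask`
#'   (a [binary_mask()] of the image's shape), `color` (RGB triple in 0-255),
#'   `style` (`"contour"` or `"filled"`), and optional `opacity` in `(0, 1]`
#'   (default 1).
#' @param path Optional output PNG path; if `NULL`, nothing is written.
#' @return The composited [raster_image()], invisibly.
#' @export
render_overlay <- function(image, layers = list(), path = NULL) {
  out <- unclass(image) * 1.0
  for (layer in layers) {
    mask <- layer$mask
    if (!identical(dim(mask), dim(out)[1:2]))
      stop("overlay layer mask shape does not match the image")
    style <- if (is.null(layer$style)) "contour" else layer$style
    opacity <- if (is.null(layer$opacity)) 1 else layer$opacity
    sel <- if (identical(style, "filled")) unclass(mask) else unclass(mask_contour(mask))
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- (1 - opacity) * plane[sel] + opacity * layer$color[ch]
      out[, , ch] <- plane
    }
  }
  out <- raster_image(out)
  if (!is.null(path)) save_image(out, path)
  invisible(out)
}
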