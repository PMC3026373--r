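#' Convert an RGB image to an intensity grid
#'
#' @param image A [raster_image()].
#' @param channel `"luminance"` (Rec. 601 weights, rounded) or one of
#'   `"red"`, `"green"`, `"blue"` for a verbatim channel.
#' @return Integer `H x W` matrix of intensities in 0-255.
#' @export
to_intensity <- function(image, channel = c("luminance", "red", "green", "blue")) {
  channel <- match.arg(channel)
  px <- unclass(image)
  out <- switch(channel,
    luminance = round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]),
    red = px[, , 1], green = px[, , 2], blue = px[, , 3])
  matrix(as.integer(out), dim(px)[1], dim(px)[2])
}

#' Otsu threshold of an 8-bit intensity grid
#'
#' Maximizes the between-class variance over the 256-bin histogram. A threshold
#' `t` splits pixels into intensity `<= t` versus `> t`; ties are broken toward
#' the smallest qualifying threshold so the result is deterministic.
#'
#' @param intensity Integer matrix with values in 0-255.
#' @return The threshold `t` in 0-254.
#' @export
otsu_threshold <- function(intensity) {
  h <- tabulate(as.integer(intensity) + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)
    stop("degenerate histogram: constant image has no separating threshold")
  p <- h / sum(h)
  w0 <- cumsum(p)[1:255]                 # class probability for t = 0..254
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (muT * w0[valid] - mu[1:255][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  which.max(sigma_b) - 1L                # which.max returns the first maximum
}

#' Binarize an image into a lesion mask
#'
#' Produces the binary (segmented) input consumed by the density-based
#' clusterer. With `polarity = "dark"` pixels at or below the threshold are
#' positive (lesions are darker than surrounding skin in dermoscopy); with
#' `"bright"`, pixels above it.
#'
#' @param image A [raster_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Threshold in 0-255; required iff `method = "fixed"`.
#' @param channel Intensity channel, see [to_intensity()].
#' @param polarity `"dark"` (default) or `"bright"`.
#' @return A [binary_mask()].
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     channel = "luminance", polarity = c("dark", "bright")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  intensity <- to_intensity(image, channel)
  t <- if (method == "otsu") {
    otsu_threshold(intensity)
  } else {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
    if (threshold < 0 || threshold > 255) stop("threshold must lie in [0, 255]")
    threshold
  }
  binary_mask(if (polarity == "dark") intensity <= t else intensity > t)
}
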