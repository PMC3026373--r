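# Manual-border construction: dermatologist-style control points joined by a
# closed (periodic) quadratic B-spline, rasterized and filled.

#' Read border control points from a plain-text file
#'
#' Two whitespace-separated columns per line, `row col` (1-based); `#` starts
#' a comment.
#'
#' @param path Path to the control-point file.
#' @return Two-column numeric matrix of `(row, col)` coordinates.
#' @export
read_control_points <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("row", "col"))
  as.matrix(tab)
}

#' Sample a closed uniform quadratic B-spline
#'
#' The control points act as de Boor points of a periodic degree-2 B-spline
#' with uniform knots. Segment `i` (one per control point) is
#' `B_i(t) = ((1-t)^2 P_{i-1} + (-2t^2 + 2t + 1) P_i + t^2 P_{i+1}) / 2`,
#' indices cyclic, `t` in `[0, 1)`.
#'
#' @param points `n x 2` matrix of control points, `n >= 3`.
#' @param samples_per_segment Samples per spline segment, `>= 2`.
#' @return Matrix of sampled curve points (`n * samples_per_segment` rows),
#'   tracing the closed curve once.
#' @export
bspline_closed_curve <- function(points, samples_per_segment = 20) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("a closed curve needs at least 3 control points")
  if (samples_per_segment < 2) stop("samples_per_segment must be >= 2")
  t <- (seq_len(samples_per_segment) - 1) / samples_per_segment
  b0 <- (1 - t)^2 / 2
  b1 <- (-2 * t^2 + 2 * t + 1) / 2
  b2 <- t^2 / 2
  prev <- points[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- points[c(seq_len(n)[-1], 1L), , drop = FALSE]
  # rows ordered segment-major: segment 1 samples, then segment 2, ...
  rows <- outer(b0, prev[, 1]) + outer(b1, points[, 1]) + outer(b2, nxt[, 1])
  cols <- outer(b0, prev[, 2]) + outer(b1, points[, 2]) + outer(b2, nxt[, 2])
  cbind(row = as.numeric(rows), col = as.numeric(cols))
}

# does segment (p1,p2) properly intersect (p3,p4)? vectorized over rows
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# error if the closed polyline self-intersects (fill is undefined then)
check_simple_polygon <- function(curve) {
  k <- nrow(curve)
  a <- curve
  b <- curve[c(2:k, 1L), , drop = FALSE]
  for (i in seq_len(k - 2L)) {
    j <- (i + 2L):k
    if (i == 1L) j <- j[j < k]          # segment k is adjacent to segment 1
    hit <- segments_intersect(a[rep(i, length(j)), , drop = FALSE],
                              b[rep(i, length(j)), , drop = FALSE],
                              a[j, , drop = FALSE], b[j, , drop = FALSE])
    if (any(hit))
      stop(sprintf("sampled border curve self-intersects (segments %d and %d)",
                   i, j[which(hit)[1]]))
  }
  invisible(curve)
}

# stamp a polyline onto a logical H x W grid with unit-thickness segments
rasterize_closed_curve <- function(curve, shape) {
  k <- nrow(curve)
  a <- curve
  b <- curve[c(2:k, 1L), , drop = FALSE]
  steps <- pmax(ceiling(pmax(abs(b[, 1] - a[, 1]), abs(b[, 2] - a[, 2]))), 1L)
  t <- sequence(steps + 1L) - 1L
  seg <- rep.int(seq_len(k), steps + 1L)
  frac <- t / steps[seg]
  r <- round(a[seg, 1] + frac * (b[seg, 1] - a[seg, 1]))
  c <- round(a[seg, 2] + frac * (b[seg, 2] - a[seg, 2]))
  grid <- matrix(FALSE, shape[1], shape[2])
  ok <- r >= 1 & r <= shape[1] & c >= 1 & c <= shape[2]
  grid[cbind(r[ok], c[ok])] <- TRUE
  grid
}

#' Filled manual-border mask from control points
#'
#' Evaluates the closed quadratic B-spline through the control points, samples
#' it densely, rasterizes the closed curve and fills its interior. This mirrors
#' how manual lesion borders are built from a dermatologist's picked points.
#'
#' @param points `n x 2` matrix of `(row, col)` control points (or a
#'   [read_control_points()] result), all inside the image.
#' @param shape Image shape `c(H, W)`.
#' @param samples_per_segment Curve samples per control point (default 20).
#' @return A [binary_mask()] of the filled border region.
#' @export
bspline_closed_mask <- function(points, shape, samples_per_segment = 20) {
  points <- as.matrix(points)
  if (any(points[, 1] < 1 | points[, 1] > shape[1] |
          points[, 2] < 1 | points[, 2] > shape[2]))
    stop("all control points must lie inside the image")
  curve <- bspline_closed_curve(points, samples_per_segment)
  check_simple_polygon(curve)
  outline <- rasterize_closed_curve(curve, shape)
  binary_mask(EBImage::fillHull(outline * 1L) > 0L)
}
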