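# Synthetic dermoscopy-like lesion images with exact ground truth.
#
# The lesion is star-convex: its boundary is an ellipse radius perturbed by a
# seeded mixture of low-order sinusoids, so the exact mask is computable
# analytically per pixel. The image blends a dark lesion color into a lighter
# skin color across a gradient band (the "fuzzy" border), then adds Gaussian
# noise and optional thin dark hair strokes. Ground truth is defined pre-noise
# and pre-hair, matching manual-border semantics: the outline delineates the
# lesion, not the artifacts.

#' Synthetic lesion configuration
#'
#' @param shape Image shape `c(H, W)` (default 200 x 200).
#' @param lesion_center Center `c(row, col)` (default image center).
#' @param lesion_axes Ellipse semi-axes `c(a, b)` in pixels (default 55, 45).
#' @param axis_angle Ellipse rotation in radians (default 0.4).
#' @param boundary_irregularity Total radial perturbation amplitude in pixels
#'   (default 3); spread over at most 4 seeded sinusoids of order 2-5.
#' @param edge_softness Width in pixels of the linear lesion/skin blend across
#'   the boundary (default 4); 0 gives a hard two-tone edge.
#' @param lesion_color,skin_color RGB triples (defaults: dark brown lesion
#'   `c(70, 40, 30)` on light skin `c(190, 150, 130)`; luminance contrast
#'   about 110 gray levels).
#' @param noise_sd Per-channel Gaussian noise SD in gray levels (default 6).
#' @param n_hairs Number of dark hair strokes crossing the lesion (default 0).
#' @param hair_width Stroke width in pixels (default 2).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(shape = c(200, 200),
                         lesion_center = (shape + 1) / 2,
                         lesion_axes = c(55, 45),
                         axis_angle = 0.4,
                         boundary_irregularity = 3,
                         edge_softness = 4,
                         lesion_color = c(70, 40, 30),
                         skin_color = c(190, 150, 130),
                         noise_sd = 6,
                         n_hairs = 0,
                         hair_width = 2) {
  cfg <- list(shape = shape, lesion_center = lesion_center,
              lesion_axes = lesion_axes, axis_angle = axis_angle,
              boundary_irregularity = boundary_irregularity,
              edge_softness = edge_softness, lesion_color = lesion_color,
              skin_color = skin_color, noise_sd = noise_sd,
              n_hairs = n_hairs, hair_width = hair_width)
  reach <- max(lesion_axes) + boundary_irregularity + edge_softness
  if (lesion_center[1] - reach < 1 || lesion_center[1] + reach > shape[1] ||
      lesion_center[2] - reach < 1 || lesion_center[2] + reach > shape[2])
    stop("lesion (axes + irregularity + edge softness) must fit inside the image")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(c(lesion_color, skin_color) < 0 | c(lesion_color, skin_color) > 255))
    stop("colors must be valid RGB triples")
  class(cfg) <- "synth_config"
  cfg
}

#' Preset synthetic configurations
#'
#' `"easy"` is the default low-noise, moderate-contrast regime; `"fuzzy"`
#' widens the border gradient and raises the noise; `"hairy"` adds hair
#' strokes to the easy regime.
#'
#' @param preset One of `"easy"`, `"fuzzy"`, `"hairy"`.
#' @param ... Overrides passed to [synth_config()].
#' @return A [synth_config()].
#' @export
synth_preset <- function(preset = c("easy", "fuzzy", "hairy"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    easy = list(),
    fuzzy = list(edge_softness = 12, noise_sd = 10, boundary_irregularity = 5),
    hairy = list(n_hairs = 4))
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# radial boundary r(theta) of the star-convex lesion; uses RNG (call seeded)
lesion_radius_fun <- function(cfg) {
  a <- cfg$lesion_axes[1]; b <- cfg$lesion_axes[2]
  n_harm <- if (cfg$boundary_irregularity > 0) sample(2:4, 1) else 0
  amp <- if (n_harm > 0) {
    raw <- stats::runif(n_harm, 0.3, 1)
    raw * cfg$boundary_irregularity / sum(raw)
  } else numeric(0)
  ord <- if (n_harm > 0) sample(2:5, n_harm) else integer(0)
  phase <- stats::runif(n_harm, 0, 2 * pi)
  force(list(a, b, amp, ord, phase))
  function(theta) {
    psi <- theta - cfg$axis_angle
    r <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
    for (k in seq_along(amp)) r <- r + amp[k] * cos(ord[k] * theta + phase[k])
    r
  }
}

# overwrite a quadratic Bezier stroke crossing near the lesion; uses RNG
stamp_hair <- function(px, cfg) {
  h <- cfg$shape[1]; w <- cfg$shape[2]
  ctr <- cfg$lesion_center
  # a chord through a point near the lesion center, extended to the margins
  anchor <- ctr + stats::runif(2, -0.5, 0.5) * cfg$lesion_axes
  ang <- stats::runif(1, 0, pi)
  dir <- c(sin(ang), cos(ang))
  span <- max(h, w) * 1.5
  p0 <- anchor - span * dir
  p2 <- anchor + span * dir
  bend <- stats::runif(1, -0.15, 0.15) * span
  p1 <- anchor + bend * c(dir[2], -dir[1])
  t <- seq(0, 1, length.out = 4L * span)
  pts <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  rad <- cfg$hair_width / 2
  off <- disc_offsets(max(rad, 0.5))
  r <- round(rep(pts[, 1], each = nrow(off)) + off[, 1])
  c <- round(rep(pts[, 2], each = nrow(off)) + off[, 2])
  ok <- r >= 1 & r <= h & c >= 1 & c <= w
  idx <- unique(r[ok] + (c[ok] - 1) * h)
  hair_color <- c(35, 25, 20)
  for (ch in 1:3) px[idx + (ch - 1) * h * w] <- hair_color[ch]
  px
}

#' Generate a synthetic lesion image with exact ground truth
#'
#' @param cfg A [synth_config()] (default [synth_preset()] `"easy"`).
#' @param seed RNG seed; outputs are bit-identical for a fixed seed.
#' @return List: `image` (a [raster_image()]), `mask` (the exact pre-noise,
#'   pre-hair ground-truth [binary_mask()]), and `cfg`.
#' @export
generate_lesion <- function(cfg = synth_preset("easy"), seed = 1) {
  withr::with_seed(seed, {
    h <- cfg$shape[1]; w <- cfg$shape[2]
    rfun <- lesion_radius_fun(cfg)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    dy <- rows - cfg$lesion_center[1]
    dx <- cols - cfg$lesion_center[2]
    rho <- sqrt(dy^2 + dx^2)
    rb <- matrix(rfun(atan2(dy, dx)), h, w)
    mask <- rho <= rb
    s <- rho - rb                        # signed distance to the boundary
    alpha <- if (cfg$edge_softness > 0) {
      pmin(pmax(0.5 - s / cfg$edge_softness, 0), 1)
    } else (s <= 0) * 1
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3)
      px[, , ch] <- alpha * cfg$lesion_color[ch] +
        (1 - alpha) * cfg$skin_color[ch]
    if (cfg$noise_sd > 0)
      px <- px + stats::rnorm(length(px), sd = cfg$noise_sd)
    px <- pmin(pmax(px, 0), 255)
    if (cfg$n_hairs > 0)
      for (i in seq_len(cfg$n_hairs)) px <- stamp_hair(px, cfg)
    list(image = raster_image(round(px)), mask = binary_mask(mask), cfg = cfg)
  })
}

#' Exact binary blob fixtures
#'
#' Union of solid discs and rectangles, for unit-testing clusterers.
#'
#' @param shape Mask shape `c(H, W)`.
#' @param specs List of specs: `list(type = "disc", center = c(r, c),
#'   radius = r)` or `list(type = "rect", rows = c(r1, r2), cols = c(c1, c2))`.
#' @return A [binary_mask()].
#' @export
generate_binary_blobs <- function(shape, specs) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (sp in specs) {
    if (identical(sp$type, "disc")) {
      off <- disc_offsets(sp$radius)
      r <- sp$center[1] + off[, 1]; c <- sp$center[2] + off[, 2]
      ok <- r >= 1 & r <= shape[1] & c >= 1 & c <= shape[2]
      m[cbind(r[ok], c[ok])] <- TRUE
    } else if (identical(sp$type, "rect")) {
      m[sp$rows[1]:sp$rows[2], sp$cols[1]:sp$cols[2]] <- TRUE
    } else stop("unknown blob spec type: ", sp$type)
  }
  binary_mask(m)
}
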