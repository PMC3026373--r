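# Fuzzy c-means (Bezdek) over pixel colors, with membership-threshold
# defuzzification for lesion segmentation.

# squared Euclidean distances, n x c
sqdist <- function(data, centers) {
  d2 <- outer(rowSums(data^2), rowSums(centers^2), `+`) -
    2 * data %*% t(centers)
  pmax(d2, 0)
}

#' Fuzzy membership update
#'
#' Computes `u_ij = 1 / sum_k (d(x_i, c_j) / d(x_i, c_k))^(2/(m-1))`. A point
#' coinciding with one or more centers gets its whole mass split equally among
#' the coincident centers (the standard singularity convention).
#'
#' @param data `n x d` numeric matrix of points.
#' @param centers `c x d` numeric matrix of cluster centers.
#' @param m Fuzzification factor, `> 1`.
#' @return `n x c` membership matrix; rows sum to 1.
#' @export
membership_update <- function(data, centers, m = 2) {
  if (m <= 1) stop("fuzzification factor m must exceed 1")
  data <- as.matrix(data); centers <- as.matrix(centers)
  d2 <- sqdist(data, centers)
  # squared distances below 1e-12 count as coincident: avoids overflow of
  # d2^(-1/(m-1)) while leaving any meaningful color distance untouched
  sing <- d2 < 1e-12
  u <- pmax(d2, 1e-12)^(-1 / (m - 1))
  hit <- rowSums(sing) > 0
  if (any(hit)) {
    u[hit, ] <- sing[hit, , drop = FALSE] * 1
  }
  u / rowSums(u)
}

#' Cluster center update
#'
#' Each center is the `u^m`-weighted mean of the data:
#' `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`.
#'
#' @inheritParams membership_update
#' @param u `n x c` membership matrix.
#' @return `c x d` matrix of centers.
#' @export
centers_update <- function(data, u, m = 2) {
  data <- as.matrix(data)
  um <- u^m
  mass <- colSums(um)
  if (any(mass == 0)) stop("degenerate cluster: a membership column has zero mass")
  t(um) %*% data / mass
}

#' Fuzzy c-means objective
#'
#' `F_m(u, c) = sum_i sum_j u_ij^m d^2(x_i, c_j)`; non-negative, and zero iff
#' every point with positive membership sits on its center.
#'
#' @inheritParams centers_update
#' @param centers `c x d` matrix of centers.
#' @return Scalar objective value.
#' @export
fcm_objective <- function(data, u, centers, m = 2) {
  sum(u^m * sqdist(as.matrix(data), as.matrix(centers)))
}

#' Fit fuzzy c-means
#'
#' Alternates the center update and the membership update from a seeded random
#' initial membership matrix, stopping when the largest absolute change in the
#' membership matrix falls below `tol` or after `max_iter` iterations.
#' Bit-reproducible for a fixed seed.
#'
#' @param data `n x d` numeric matrix.
#' @param c Number of clusters.
#' @param m Fuzzification factor (default 2).
#' @param tol Convergence threshold on `max |U^(k+1) - U^(k)|` (default 1e-5).
#' @param max_iter Iteration cap (default 300).
#' @param seed RNG seed for the initial membership matrix.
#' @return List of class `fcm_fit`: `u` (n x c memberships), `centers`
#'   (c x d), `objective_trace` (per-iteration objective, non-increasing),
#'   `iterations`, and `converged` (FALSE when `max_iter` was hit).
#' @export
fcm_fit <- function(data, c, m = 2, tol = 1e-5, max_iter = 300, seed = 1) {
  if (c < 1) stop("c must be at least 1")
  if (m <= 1) stop("fuzzification factor m must exceed 1")
  if (tol <= 0 || max_iter < 1) stop("tol must be positive and max_iter >= 1")
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < c) warning("fewer data points than clusters")
  u <- withr::with_seed(seed, matrix(stats::runif(n * c), n, c))
  u <- u / rowSums(u)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    centers <- centers_update(data, u, m)
    u_new <- membership_update(data, centers, m)
    trace[iter] <- fcm_objective(data, u_new, centers, m)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(u = u, centers = centers, objective_trace = trace,
                 iterations = iter, converged = converged),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("<fcm_fit: %d points, %d clusters, %d iterations, %s>\n",
              nrow(x$u), ncol(x$u), x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Rec. 601 luminance of c x 3 color coordinates
center_luminance <- function(centers) {
  drop(centers %*% c(0.299, 0.587, 0.114))
}

#' Segment an image by fuzzy c-means on pixel colors
#'
#' Fits FCM to the `H*W` pixel RGB triples. Each pixel whose maximum membership
#' falls below `T/100` is left unclassified; the rest take their argmax cluster
#' (ties toward the lowest index). The lesion cluster is the one whose center
#' has minimum luminance (the darkest — lesions are darker than skin), unless
#' overridden; its pixel set is reduced to the largest connected component and
#' hole-filled.
#'
#' @param image A [raster_image()].
#' @param c Number of clusters (default 5).
#' @param m Fuzzification factor (default 2).
#' @param T Defuzzification threshold, percent membership in (0, 100)
#'   (default 30).
#' @param tol,max_iter,seed Passed to [fcm_fit()].
#' @param lesion_cluster `"auto"` (darkest center) or an explicit cluster index.
#' @return List: `mask` (the lesion [binary_mask()]), `labels` (`H x W`
#'   integer assignment map, 0 = unclassified), and `fit` (the [fcm_fit()]
#'   object).
#' @export
fcm_segment_image <- function(image, c = 5, m = 2, T = 30, tol = 1e-5,
                              max_iter = 300, seed = 1,
                              lesion_cluster = "auto") {
  if (T <= 0 || T >= 100) stop("T must lie in (0, 100)")
  px <- unclass(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  data <- cbind(as.numeric(px[, , 1]), as.numeric(px[, , 2]),
                as.numeric(px[, , 3]))
  fit <- fcm_fit(data, c = c, m = m, tol = tol, max_iter = max_iter,
                 seed = seed)
  assign <- max.col(fit$u, ties.method = "first")
  maxu <- fit$u[cbind(seq_len(nrow(fit$u)), assign)]
  assign[maxu < T / 100] <- 0L          # unclassified
  labels <- matrix(as.integer(assign), h, w)

  lesion <- if (identical(lesion_cluster, "auto")) {
    which.min(center_luminance(fit$centers))
  } else as.integer(lesion_cluster)
  m_raw <- labels == lesion
  if (!any(m_raw)) {
    warning("no pixel assigned to the lesion cluster; returning an empty mask")
    return(list(mask = binary_mask(m_raw), labels = labels, fit = fit))
  }
  comp <- EBImage::bwlabel(m_raw * 1L)
  counts <- tabulate(comp[comp > 0L])
  keep <- comp == which.max(counts)
  mask <- binary_mask(EBImage::fillHull(keep * 1L) > 0L)
  list(mask = mask, labels = labels, fit = fit)
}
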