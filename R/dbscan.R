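# Grid-adapted DBSCAN over the positive pixels of a binary mask.
#
# Label conventions in the returned label map:
#   0  = background (negative pixel, never a cluster member)
#   -1 = noise (positive pixel belonging to no cluster)
#   1..k = cluster IDs, consecutive in first-assignment (row-major) order
# During the scan, unclassified positive pixels are held as NA.

NOISE_LABEL <- -1L
BACKGROUND_LABEL <- 0L

#' Integer lattice offsets of the Eps disc
#'
#' All integer `(dr, dc)` with `dr^2 + dc^2 <= eps^2`; the region-query stencil.
#'
#' @param eps Neighborhood radius in pixels (Euclidean).
#' @return Two-column integer matrix of offsets.
#' @export
disc_offsets <- function(eps) {
  if (eps < 0) stop("eps must be non-negative")
  r <- floor(eps)
  g <- expand.grid(dr = (-r):r, dc = (-r):r)
  keep <- g$dr^2 + g$dc^2 <= eps^2
  cbind(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]))
}

# linear (column-major) indices of in-bounds positive pixels within eps of the
# pixel at linear index idx; offsets = disc_offsets(eps)
neighborhood_idx <- function(mask, idx, offsets, h, w) {
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  rr <- r + offsets[, 1L]
  cc <- c + offsets[, 2L]
  ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
  cand <- as.integer(rr[ok] + (cc[ok] - 1L) * h)
  cand[mask[cand]]
}

#' Eps-neighborhood of a pixel
#'
#' Returns every in-bounds positive pixel `q` with Euclidean distance
#' `dist(p, q) <= eps`, including `p` itself when `p` is positive. Image
#' borders simply truncate the disc.
#'
#' @param mask A [binary_mask()].
#' @param p Pixel coordinate `c(row, col)`, 1-based.
#' @param eps Neighborhood radius in pixels.
#' @return Two-column integer matrix of `(row, col)` coordinates.
#' @export
eps_neighborhood <- function(mask, p, eps) {
  h <- nrow(mask); w <- ncol(mask)
  if (length(p) != 2L || p[1] < 1L || p[1] > h || p[2] < 1L || p[2] > w)
    stop("pixel p lies outside the image grid")
  idx <- neighborhood_idx(unclass(mask), p[1] + (p[2] - 1L) * h,
                          disc_offsets(eps), h, w)
  cbind(row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L)
}

# workhorse shared by expand_cluster() and dbscan_mask(); labels is modified
# and returned in a list to keep R copy semantics explicit
expand_cluster_impl <- function(mask, labels, seed_idx, cluster_id, offsets,
                                min_pxl, h, w) {
  nb <- neighborhood_idx(mask, seed_idx, offsets, h, w)
  if (length(nb) < min_pxl) {
    labels[seed_idx] <- NOISE_LABEL
    return(list(expanded = FALSE, labels = labels))
  }
  labels[nb] <- cluster_id
  queue <- integer(sum(mask))
  n_q <- length(nb)
  queue[seq_len(n_q)] <- nb
  head <- 1L
  while (head <= n_q) {
    q <- queue[head]; head <- head + 1L
    qnb <- neighborhood_idx(mask, q, offsets, h, w)
    if (length(qnb) >= min_pxl) {       # q is core: its whole disc joins
      lt <- labels[qnb]
      fresh <- qnb[is.na(lt)]           # unclassified: join and expand from
      if (length(fresh)) {
        labels[fresh] <- cluster_id
        queue[n_q + seq_along(fresh)] <- fresh
        n_q <- n_q + length(fresh)
      }
      reclaimed <- qnb[!is.na(lt) & lt == NOISE_LABEL]
      if (length(reclaimed)) labels[reclaimed] <- cluster_id  # border pixels
    }
  }
  list(expanded = TRUE, labels = labels)
}

#' Grow one cluster from a seed pixel
#'
#' Applies the core-pixel test to `seed`: if its Eps-neighborhood holds fewer
#' than `min_pxl` positive pixels the seed is marked noise and nothing else
#' changes. Otherwise the seed's whole neighborhood joins the cluster and the
#' cluster is grown through a work queue of its members: every member that is
#' itself core pulls in its neighborhood; noise pixels encountered are
#' relabeled as border pixels of the cluster.
#'
#' @param mask A [binary_mask()].
#' @param labels Integer label matrix (see [dbscan_mask()]); the seed must be
#'   unclassified (`NA`).
#' @param seed Pixel coordinate `c(row, col)`, 1-based; must be positive.
#' @param cluster_id Integer ID to assign.
#' @param eps,min_pxl Density parameters.
#' @return List with `expanded` (logical) and the updated `labels` matrix.
#' @export
expand_cluster <- function(mask, labels, seed, cluster_id, eps, min_pxl) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- seed[1] + (seed[2] - 1L) * h
  if (!mask[idx]) stop("seed pixel is not positive")
  if (!is.na(labels[idx])) stop("seed pixel is already classified")
  expand_cluster_impl(unclass(mask), labels, idx, as.integer(cluster_id),
                      disc_offsets(eps), min_pxl, h, w)
}

#' Density-based clustering of a binary mask
#'
#' Scans the grid row-major from the top-left; each unclassified positive pixel
#' whose Eps-neighborhood holds at least `min_pxl` positive pixels seeds a new
#' cluster grown by [expand_cluster()]. Seeds failing the core test are
#' provisionally noise but may later be absorbed as border pixels of another
#' cluster. Fully deterministic given the mask and parameters.
#'
#' @param mask A [binary_mask()].
#' @param eps Neighborhood radius in pixels (default 5).
#' @param min_pxl Minimum positive-pixel count for a core pixel (default 60).
#' @return Integer `H x W` label matrix: 0 background, -1 noise, clusters
#'   numbered 1..k in first-assignment order.
#' @export
dbscan_mask <- function(mask, eps = 5, min_pxl = 60) {
  if (eps <= 0) stop("eps must be positive")
  if (min_pxl < 1) stop("min_pxl must be at least 1")
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  labels <- matrix(BACKGROUND_LABEL, h, w)
  labels[m] <- NA_integer_
  offsets <- disc_offsets(eps)

  pos <- which(m)
  pr <- ((pos - 1L) %% h) + 1L
  pc <- ((pos - 1L) %/% h) + 1L
  pos <- pos[order(pr, pc)]             # row-major seed order from (1, 1)

  cluster_id <- 0L
  for (idx in pos) {
    if (!is.na(labels[idx])) next
    res <- expand_cluster_impl(m, labels, idx, cluster_id + 1L, offsets,
                               min_pxl, h, w)
    labels <- res$labels
    if (res$expanded) cluster_id <- cluster_id + 1L
  }
  labels
}

#' Extract the lesion mask from a clustering
#'
#' @param labels Label matrix from [dbscan_mask()].
#' @param policy `"largest"` (default) keeps the cluster with the most pixels,
#'   ties broken toward the lowest ID; `"all"` keeps the union of all clusters.
#' @param fill_holes Fill interior holes of the selected region (default
#'   `TRUE`): the lesion is a solid region and border error is computed on
#'   filled regions.
#' @return A [binary_mask()]; empty (with a warning) when no cluster exists.
#' @export
select_lesion_mask <- function(labels, policy = c("largest", "all"),
                               fill_holes = TRUE) {
  policy <- match.arg(policy)
  k <- max(labels, 0L)
  if (k == 0L) {
    warning("clustering found no cluster; returning an empty mask")
    return(binary_mask(matrix(FALSE, nrow(labels), ncol(labels))))
  }
  m <- if (policy == "all") labels > 0L else {
    counts <- tabulate(labels[labels > 0L], nbins = k)
    labels == which.max(counts)
  }
  if (fill_holes) m <- EBImage::fillHull(m * 1L) > 0L
  binary_mask(m)
}
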