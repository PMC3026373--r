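# Independent reference implementations used as oracles. These deliberately
# use brute force (pairwise distances, explicit loops) and share no code with
# the package internals they check.

random_mask <- function(h, w, density) {
  binary_mask(matrix(stats::runif(h * w) < density, h, w))
}

# brute-force density-reachability closure over the positive pixels:
# core flags, core-graph components, and for every non-core positive pixel the
# set of components owning a core within eps
oracle_dbscan <- function(mask, eps, min_pxl) {
  coords <- which(unclass(mask), arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0)
    return(list(coords = coords, core = logical(0), comp = integer(0),
                reach = list()))
  dr <- outer(coords[, 1], coords[, 1], "-")
  dc <- outer(coords[, 2], coords[, 2], "-")
  within <- dr * dr + dc * dc <= eps^2
  core <- rowSums(within) >= min_pxl
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      nb <- which(within[q, ] & core & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  reach <- lapply(seq_len(n), function(i) {
    if (core[i]) return(comp[i])
    sort(unique(comp[within[i, ] & core]))
  })
  list(coords = coords, core = core, comp = comp, reach = reach)
}

# does an implementation label map agree with the closure oracle?
# Equality up to cluster-ID renaming, allowing the documented tie-break for
# border pixels reachable from more than one cluster. Returns TRUE or a
# message describing the first disagreement.
dbscan_matches_oracle <- function(labels, mask, eps, min_pxl) {
  o <- oracle_dbscan(mask, eps, min_pxl)
  if (any(labels[!unclass(mask)] != 0))
    return("a negative pixel carries a non-background label")
  if (nrow(o$coords) == 0) return(TRUE)
  lab <- labels[o$coords]
  if (any(is.na(lab))) return("an unclassified positive pixel remains")
  is_noise_oracle <- vapply(o$reach, length, 1L) == 0
  if (!identical(unname(lab == -1), unname(is_noise_oracle)))
    return("noise sets differ")
  # core partition must match up to a bijective relabeling
  map <- tapply(lab[o$core], o$comp[o$core], unique, simplify = FALSE)
  if (any(lengths(map) != 1))
    return("an oracle core component carries two implementation labels")
  map <- unlist(map)
  if (anyDuplicated(map))
    return("two oracle core components share one implementation label")
  if (any(map <= 0)) return("a core pixel is labeled noise or background")
  # each border pixel must sit in a cluster with a core within eps of it
  border <- !o$core & !is_noise_oracle
  ok <- vapply(which(border), function(i) lab[i] %in% map[o$reach[[i]]], TRUE)
  if (!all(ok)) return("a border pixel joined a cluster that cannot reach it")
  TRUE
}

# 8-connected component labeling by breadth-first search
label_components8 <- function(mask) {
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  labels <- matrix(0L, h, w)
  off <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  off <- off[rowSums(abs(off)) > 0, ]
  cid <- 0L
  for (start in which(m)) {
    if (labels[start] != 0L) next
    cid <- cid + 1L
    queue <- start
    labels[start] <- cid
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- ((q - 1L) %% h) + 1L
      c <- ((q - 1L) %/% h) + 1L
      rr <- r + off[, 1]; cc <- c + off[, 2]
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      nb <- rr[ok] + (cc[ok] - 1L) * h
      nb <- nb[m[nb] & labels[nb] == 0L]
      labels[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  labels
}

# are two label maps identical partitions of the positive pixels, up to
# renaming of the cluster IDs?
same_partition <- function(a, b, mask) {
  ka <- a[unclass(mask)]; kb <- b[unclass(mask)]
  if (!identical(ka > 0, kb > 0)) return(FALSE)
  pos <- ka > 0
  pairs <- unique(cbind(ka[pos], kb[pos]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# exhaustive 256-threshold Otsu scan
oracle_otsu <- function(intensity) {
  v <- as.integer(intensity)
  n <- length(v)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    lo <- v <= t
    n0 <- sum(lo); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    s <- (n0 / n) * (n1 / n) * (mean(v[lo]) - mean(v[!lo]))^2
    if (s > best) { best <- s; bt <- t }
  }
  bt
}

# shoelace area of a closed polygon given as an ordered vertex matrix
shoelace_area <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# boundary pixels by 4-neighbor erosion difference (independent of the
# package's contour routine)
oracle_contour <- function(mask) {
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!m[i, j]) next
    nb <- c(if (i > 1) m[i - 1, j] else FALSE,
            if (i < h) m[i + 1, j] else FALSE,
            if (j > 1) m[i, j - 1] else FALSE,
            if (j < w) m[i, j + 1] else FALSE)
    out[i, j] <- !all(nb)
  }
  out
}
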