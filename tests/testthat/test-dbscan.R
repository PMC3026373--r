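test_that("eps-neighborhood truncates at image borders and respects polarity", {
  all_neg <- binary_mask(matrix(FALSE, 10, 10))
  expect_equal(nrow(eps_neighborhood(all_neg, c(5, 5), 3)), 0)

  one <- binary_mask(matrix(FALSE, 5, 5))
  one[3, 3] <- TRUE
  nb <- eps_neighborhood(one, c(3, 3), 0)
  expect_identical(nb, cbind(row = 3L, col = 3L))

  all_pos <- binary_mask(matrix(TRUE, 7, 7))
  corner <- eps_neighborhood(all_pos, c(1, 1), 2)
  expect_equal(nrow(corner), sum(outer(0:2, 0:2, function(a, b) a^2 + b^2) <= 4))

  expect_error(eps_neighborhood(all_pos, c(0, 3), 2), "outside")
})

test_that("degenerate masks cluster correctly", {
  empty <- binary_mask(matrix(FALSE, 6, 6))
  lab <- dbscan_mask(empty, eps = 2, min_pxl = 3)
  expect_true(all(lab == 0L))

  single <- binary_mask(matrix(FALSE, 6, 6))
  single[4, 4] <- TRUE
  lab <- dbscan_mask(single, eps = 1, min_pxl = 1)
  expect_equal(sum(lab == 1L), 1)
  expect_equal(max(lab), 1L)
})

test_that("sparse blocks below the density threshold become noise", {
  # solid 10x10 square plus a distant 2x2 block: with eps = 1.5 the block's
  # best neighborhood holds 4 pixels < min_pxl = 5, so one cluster + 4 noise
  m <- generate_binary_blobs(c(30, 30), list(
    list(type = "rect", rows = c(2, 11), cols = c(2, 11)),
    list(type = "rect", rows = c(20, 21), cols = c(20, 21))))
  lab <- dbscan_mask(m, eps = 1.5, min_pxl = 5)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab == -1L), 4)
  expect_equal(sum(lab == 1L), 100)
})

test_that("expand_cluster honors the core test and labels reachable pixels", {
  m <- generate_binary_blobs(c(25, 25), list(
    list(type = "disc", center = c(13, 13), radius = 10)))
  labels <- matrix(0L, 25, 25)
  labels[unclass(m)] <- NA_integer_

  # an interior seed floods the whole disc (here density-reachability equals
  # 8-connectivity because eps = 1.5, and the disc is one component)
  res <- expand_cluster(m, labels, c(13, 13), 1L, eps = 1.5, min_pxl = 5)
  expect_true(res$expanded)
  expect_identical(res$labels == 1L, unclass(m))

  # a failed core test marks only the seed as noise
  iso <- binary_mask(matrix(FALSE, 9, 9))
  iso[5, 5] <- TRUE; iso[5, 6] <- TRUE
  labels2 <- matrix(0L, 9, 9); labels2[unclass(iso)] <- NA_integer_
  res2 <- expand_cluster(iso, labels2, c(5, 5), 1L, eps = 1, min_pxl = 3)
  expect_false(res2$expanded)
  expect_equal(res2$labels[5, 5], -1L)
  expect_true(is.na(res2$labels[5, 6]))

  expect_error(expand_cluster(iso, labels2, c(1, 1), 1L, 1, 3), "not positive")
})

test_that("cluster membership and the core partition ignore scan order", {
  # Border pixels reachable from two clusters follow the documented
  # first-reached tie-break, so only the core partition and the member/noise
  # sets are scan-order invariants.
  set.seed(31)
  for (i in 1:10) {
    m <- random_mask(20, 25, stats::runif(1, 0.3, 0.6))
    lab <- dbscan_mask(m, eps = 2, min_pxl = 4)
    lab_t <- t(dbscan_mask(binary_mask(t(unclass(m))), eps = 2, min_pxl = 4))
    expect_identical(lab > 0, lab_t > 0)
    expect_identical(lab == -1, lab_t == -1)
    pos <- which(unclass(m), arr.ind = TRUE)
    core <- vapply(seq_len(nrow(pos)), function(k)
      nrow(eps_neighborhood(m, pos[k, ], 2)) >= 4, TRUE)
    core_m <- matrix(FALSE, 20, 25); core_m[pos[core, , drop = FALSE]] <- TRUE
    expect_true(same_partition(lab, lab_t, binary_mask(core_m)))
  }
})

test_that("lowering min_pxl never shrinks the core-pixel set", {
  set.seed(13)
  m <- random_mask(25, 25, 0.5)
  core_set <- function(min_pxl) {
    pos <- which(unclass(m), arr.ind = TRUE)
    vapply(seq_len(nrow(pos)), function(i)
      nrow(eps_neighborhood(m, pos[i, ], 2)) >= min_pxl, TRUE)
  }
  for (mp in 2:6) expect_true(all(!core_set(mp) | core_set(mp - 1)))
})

test_that("lesion selection keeps the largest cluster and fills holes", {
  m <- generate_binary_blobs(c(40, 40), list(
    list(type = "rect", rows = c(2, 21), cols = c(2, 16)),   # 300 pixels
    list(type = "rect", rows = c(30, 37), cols = c(30, 34))  # 40 pixels
  ))
  lab <- dbscan_mask(m, eps = 1.5, min_pxl = 4)
  expect_equal(max(lab), 2L)
  sel <- select_lesion_mask(lab, policy = "largest")
  expect_equal(mask_area(sel), 300)
  both <- select_lesion_mask(lab, policy = "all")
  expect_equal(mask_area(both), 340)

  # an annulus-shaped cluster fills to the disc
  ring <- generate_binary_blobs(c(31, 31), list(
    list(type = "disc", center = c(16, 16), radius = 10)))
  hole <- generate_binary_blobs(c(31, 31), list(
    list(type = "disc", center = c(16, 16), radius = 5)))
  ring <- binary_mask(unclass(ring) & !unclass(hole))
  lab_ring <- dbscan_mask(ring, eps = 1.5, min_pxl = 4)
  filled <- select_lesion_mask(lab_ring)
  # oracle: flood-fill of the background from the image border
  outside <- label_components8(binary_mask(!unclass(ring)))
  border_ids <- unique(c(outside[1, ], outside[31, ], outside[, 1],
                         outside[, 31]))
  fill_oracle <- matrix(!(outside %in% setdiff(border_ids, 0L)), 31, 31)
  expect_identical(unclass(filled), fill_oracle)

  expect_warning(sel0 <- select_lesion_mask(matrix(0L, 5, 5)), "no cluster")
  expect_equal(mask_area(sel0), 0)
})
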