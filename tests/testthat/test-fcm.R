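test_that("membership update matches the closed form", {
  # one cluster: all mass on it
  u <- membership_update(matrix(1:4), matrix(2.5), m = 2)
  expect_true(all(u == 1))

  # equidistant point splits evenly
  u <- membership_update(matrix(0), matrix(c(-2, 2)), m = 2)
  expect_equal(unname(u[1, ]), c(0.5, 0.5))

  # 1-D: x = 0, centers {1, 3}, m = 2 -> u = (d2^2, d1^2)/(d1^2 + d2^2)
  u <- membership_update(matrix(0), matrix(c(1, 3)), m = 2)
  expect_equal(unname(u[1, ]), c(0.9, 0.1))

  # singularity: coincidence with one center is crisp; with two, split
  u <- membership_update(matrix(c(1, 5)), matrix(c(1, 3)), m = 2)
  expect_equal(unname(u[1, ]), c(1, 0))
  u <- membership_update(matrix(2), matrix(c(2, 2, 7)), m = 2)
  expect_equal(unname(u[1, ]), c(0.5, 0.5, 0))

  expect_error(membership_update(matrix(0), matrix(1), m = 1), "exceed 1")
})

test_that("center update is the u^m-weighted mean", {
  data <- matrix(c(0, 2, 10, 12), 4, 1)
  crisp <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(unname(centers_update(data, crisp, m = 2)),
               matrix(c(1, 11), 2, 1))

  even <- matrix(0.5, 4, 2)
  expect_equal(unname(centers_update(data, even, m = 2)),
               matrix(c(6, 6), 2, 1))

  u <- cbind(c(0.8, 0.2), c(0.2, 0.8))
  got <- centers_update(matrix(c(0, 2), 2, 1), u, m = 2)
  expect_equal(got[1, 1], 2 / 17)

  # centers stay inside the data bounding box
  set.seed(5)
  d <- matrix(stats::rnorm(60), 20, 3)
  u <- matrix(stats::runif(40), 20, 2); u <- u / rowSums(u)
  ctr <- centers_update(d, u, m = 2)
  for (j in 1:3)
    expect_true(all(ctr[, j] >= min(d[, j]) & ctr[, j] <= max(d[, j])))

  expect_error(centers_update(data, cbind(c(1, 1, 1, 1), 0), m = 2),
               "degenerate")
})

test_that("the objective is non-negative and zero only at perfect fits", {
  expect_equal(fcm_objective(matrix(c(1, 3)), cbind(c(1, 0), c(0, 1)),
                             matrix(c(1, 3)), m = 2), 0)
  expect_equal(fcm_objective(matrix(1), matrix(1), matrix(0), m = 2), 1)
})

test_that("one alternation cycle never increases the objective", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:40, 1); k <- sample(2:4, 1)
    data <- matrix(stats::rnorm(n * 2, sd = 3), n, 2)
    u <- matrix(stats::runif(n * k), n, k); u <- u / rowSums(u)
    ctr0 <- centers_update(data, u, m = 2)
    f0 <- fcm_objective(data, u, ctr0, m = 2)
    u1 <- membership_update(data, ctr0, m = 2)
    expect_equal(unname(rowSums(u1)), rep(1, n), tolerance = 1e-9)
    ctr1 <- centers_update(data, u1, m = 2)
    f1 <- fcm_objective(data, u1, ctr1, m = 2)
    expect_lte(f1, f0 + 1e-9)
  }
})

test_that("fcm_fit converges, is seed-reproducible and flags non-convergence", {
  set.seed(23)
  data <- rbind(matrix(stats::rnorm(100, 0, 1), 50, 2),
                matrix(stats::rnorm(100, 20, 1), 50, 2))
  fit1 <- fcm_fit(data, c = 2, seed = 4)
  fit2 <- fcm_fit(data, c = 2, seed = 4)
  expect_identical(fit1, fit2)
  expect_true(fit1$converged)
  expect_true(all(diff(fit1$objective_trace) <= 1e-9))
  expect_equal(unname(rowSums(fit1$u)), rep(1, 100), tolerance = 1e-9)

  hard <- fcm_fit(data, c = 2, seed = 4, max_iter = 1)
  expect_false(hard$converged)

  # c = 1: center is the data mean, membership all 1
  one <- fcm_fit(data, c = 1, seed = 9)
  expect_equal(unname(one$centers[1, ]), unname(colMeans(data)))
  expect_true(all(one$u == 1))
})

test_that("duplicating every point leaves the center update unchanged", {
  set.seed(29)
  data <- matrix(stats::rnorm(60), 30, 2)
  u <- matrix(stats::runif(60), 30, 2); u <- u / rowSums(u)
  expect_equal(centers_update(data, u, m = 2),
               centers_update(rbind(data, data), rbind(u, u), m = 2))
})

test_that("memberships approach crispness as m approaches 1", {
  set.seed(41)
  data <- rbind(matrix(stats::rnorm(60, 0, 0.5), 30, 2),
                matrix(stats::rnorm(60, 30, 0.5), 30, 2))
  fit <- fcm_fit(data, c = 2, m = 1.05, seed = 2)
  expect_true(all(apply(fit$u, 1, max) >= 0.99))
})

test_that("converged centers agree with an independent FCM implementation", {
  set.seed(37)
  data <- rbind(matrix(stats::rnorm(300, 0, 2), 100, 3),
                matrix(stats::rnorm(300, 60, 2), 100, 3),
                matrix(stats::rnorm(300, 150, 2), 100, 3))
  fit <- fcm_fit(data, c = 3, seed = 6)
  ref <- e1071::cmeans(data, centers = 3, m = 2, iter.max = 300)
  ord <- function(x) x[order(x[, 1]), ]
  expect_equal(ord(unname(fit$centers)), ord(unname(ref$centers)),
               tolerance = 0.05)
})

test_that("image segmentation recovers a two-tone lesion and obeys T", {
  g <- generate_lesion(synth_config(shape = c(80, 80), lesion_axes = c(22, 18),
                                    noise_sd = 2, edge_softness = 0,
                                    boundary_irregularity = 0), seed = 5)
  seg <- fcm_segment_image(g$image, c = 2, T = 30, seed = 2)
  iou <- sum(seg$mask & g$mask) / sum(seg$mask | g$mask)
  expect_gte(iou, 0.95)

  # near-crisp memberships: a high threshold classifies the same pixels
  seg99 <- fcm_segment_image(g$image, c = 2, T = 99, seed = 2)
  expect_identical(unclass(seg99$mask), unclass(seg$mask))

  # raising T never grows the classified set
  classified <- function(T) sum(fcm_segment_image(g$image, c = 2, T = T,
                                                  seed = 2)$labels > 0)
  sizes <- vapply(c(30, 50, 70, 90), classified, 1)
  expect_true(all(diff(sizes) <= 0))
})
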