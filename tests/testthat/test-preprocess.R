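make_volume <- function(values, dims = NULL) {
  dims <- dims %||% c(length(values), 1, 1)
  gray_volume(array(values, dims))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
full_mask <- function(vol) binary_mask(array(TRUE, dim(vol$voxels)))

test_that("landmark fitting recovers masked percentiles (quantile oracle)", {
  set.seed(3)
  v <- make_volume(sample(0:8191, 5000, replace = TRUE))
  m <- full_mask(v)
  map <- fit_landmark_map(v, m, percentiles = seq(10, 90, by = 10))
  expect_equal(map$source_landmarks,
               unname(stats::quantile(as.numeric(v$voxels),
                                      seq(0.1, 0.9, 0.1), type = 7)))
  expect_error(fit_landmark_map(make_volume(rep(5L, 100)),
                                binary_mask(array(TRUE, c(100, 1, 1)))),
               "constant|dynamic range")
})

test_that("standardization is invariant under positive affine input maps", {
  set.seed(8)
  base <- sample(50:4000, 4000, replace = TRUE)
  v1 <- make_volume(base)
  m <- full_mask(v1)
  s1 <- standardize(v1, fit_landmark_map(v1, m))
  for (ab in list(c(2, 10), c(3, 7), c(5, 1))) {
    v2 <- make_volume(as.integer(ab[1] * base + ab[2]))
    s2 <- standardize(v2, fit_landmark_map(v2, m))
    expect_identical(s1$voxels, s2$voxels)
  }
})

test_that("standardize maps knots exactly, interpolates midpoints, clips tails", {
  map <- structure(list(source_landmarks = c(100, 200, 400),
                        target_landmarks = c(0, 1000, 5000),
                        percentiles = c(1, 50, 99),
                        target_levels = 8192L),
                   class = "landmark_map")
  v <- make_volume(c(100L, 200L, 400L, 300L, 0L, 60000L))
  out <- standardize(v, map)$voxels
  expect_equal(out[1:3], c(0L, 1000L, 5000L))     # knots exact
  expect_equal(out[4], 3000L)                     # midpoint of segment
  expect_equal(out[5], 0L)                        # clipped below
  expect_equal(out[6], 8191L)                     # clipped above
  # monotone non-decreasing
  set.seed(1)
  x <- sort(sample(0:3000, 500))
  sx <- standardize(make_volume(x), map)$voxels
  expect_true(all(diff(as.numeric(sx)) >= 0))
})

test_that("standardization is idempotent up to integer rounding", {
  set.seed(5)
  v <- make_volume(round(stats::rnorm(20000, 9000, 1500)))
  m <- full_mask(v)
  s1 <- standardize(v, fit_landmark_map(v, m))
  s2 <- standardize(s1, fit_landmark_map(s1, m))
  expect_lte(max(abs(s2$voxels - s1$voxels)), 2)
  expect_lt(mean(abs(s2$voxels - s1$voxels)), 0.75)
})

test_that("cohort standard scale averages anchored landmark positions", {
  set.seed(10)
  vols <- lapply(1:3, function(i)
    make_volume(round(stats::rnorm(5000, 1000 * i, 150 * i)) + 2000L))
  masks <- lapply(vols, full_mask)
  std <- fit_standard_scale(vols, masks)
  expect_equal(std[1], 0)
  expect_equal(std[length(std)], 0.85 * 8191, tolerance = 1e-9)
  expect_true(all(diff(std) > 0))
})

test_that("FCM recovers well-separated intensity plateaus", {
  set.seed(21)
  n <- 3000
  truth <- sample(1:3, n, replace = TRUE)
  means <- c(500, 3000, 6000)
  x <- round(stats::rnorm(n, means[truth], 50))
  v <- make_volume(pmax(x, 0L))
  m <- full_mask(v)
  tm <- fcm_tissue_segmentation(v, m)
  expect_gte(mean(tm$hard_labels[seq_len(n)] == truth), 0.99)
  expect_equal(tm$class_centers, means, tolerance = 0.02)
  # FCM objective is non-increasing
  expect_true(all(diff(tm$objective) <= 1e-6 * tm$objective[1]))
  # memberships sum to one
  expect_true(all(abs(rowSums(tm$memberships) - 1) < 1e-9))
  # a voxel at a final center prefers that class
  centers <- round(tm$class_centers)
  v2 <- make_volume(c(centers, x))
  tm2 <- fcm_tissue_segmentation(v2, full_mask(v2))
  for (k in 1:3) expect_equal(which.max(tm2$memberships[k, ]), k)
})

test_that("FCM is deterministic and rejects degenerate inputs", {
  set.seed(33)
  v <- make_volume(sample(0:100, 2000, replace = TRUE))
  m <- full_mask(v)
  a <- fcm_tissue_segmentation(v, m)
  b <- fcm_tissue_segmentation(v, m)
  expect_identical(a$hard_labels, b$hard_labels)
  expect_identical(a$class_centers, b$class_centers)
  expect_error(fcm_tissue_segmentation(make_volume(rep(c(1L, 2L), 50)),
                                       binary_mask(array(TRUE, c(100, 1, 1))),
                                       n_classes = 3),
               "distinct")
})

test_that("FCM centers agree with e1071::cmeans on the same data", {
  skip_if_not_installed("e1071")
  set.seed(44)
  x <- round(c(stats::rnorm(400, 1000, 80), stats::rnorm(400, 4000, 120),
               stats::rnorm(400, 7000, 100)))
  v <- make_volume(x)
  tm <- fcm_tissue_segmentation(v, full_mask(v), tol = 1e-8)
  ref <- e1071::cmeans(matrix(x, ncol = 1), centers = matrix(c(1000, 4000, 7000)),
                       m = 2, iter.max = 300)
  expect_equal(tm$class_centers, sort(as.numeric(ref$centers)),
               tolerance = 1e-3)
})
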