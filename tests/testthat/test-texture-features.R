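test_that("histogram features match closed forms", {
  # constant patch: degenerate conventions
  hf <- histogram_features(matrix(42, 5, 5))
  expect_equal(hf$variance, 0)
  expect_equal(hf$energy, 1)
  expect_equal(hf$entropy, 0)
  expect_equal(hf$skewness, 0)
  expect_equal(hf$kurtosis, 0)
  # two equiprobable levels {0, g}
  g <- 600
  hf2 <- histogram_features(matrix(c(0, g), 4, 4))
  expect_equal(hf2$mean, g / 2)
  expect_equal(hf2$entropy, 1)
  expect_equal(hf2$energy, 0.5)
  expect_equal(hf2$variance, (g / 2)^2)
  expect_equal(hf2$skewness, 0)
  # moment oracle on many draws: symmetric -> |skew| small, Gaussian kurtosis ~ 3
  set.seed(99)
  x <- round(stats::rnorm(1e5, 4000, 300))
  hf3 <- histogram_features(matrix(x, ncol = 1))
  expect_lt(abs(hf3$skewness), 0.05)
  expect_equal(hf3$kurtosis, 3, tolerance = 0.1 / 3)
  expect_equal(hf3$mean, mean(x))
  expect_error(histogram_features(matrix(1, 2, 2), matrix(FALSE, 2, 2)),
               "empty")
})

test_that("k-means quantization is exact at L = distinct count and deterministic", {
  patch <- matrix(rep(c(100, 900, 2500, 7000), each = 6), 4, 6, byrow = TRUE)
  q <- kmeans_quantize(patch, n_clusters = 4)
  expect_equal(q$centers, c(100, 900, 2500, 7000))
  expect_identical(reconstruct_patch(q), patch)
  # determinism
  set.seed(1)
  p2 <- matrix(sample(0:8191, 100), 10, 10)
  expect_identical(kmeans_quantize(p2, n_clusters = 5)$labels,
                   kmeans_quantize(p2, n_clusters = 5)$labels)
  # two tight blobs, L = 2
  set.seed(2)
  blob <- matrix(round(c(stats::rnorm(50, 1000, 10),
                         stats::rnorm(50, 7000, 10))), 10, 10)
  qb <- kmeans_quantize(blob, n_clusters = 2)
  expect_true(all(qb$labels[blob < 4000] == 0))
  expect_true(all(qb$labels[blob > 4000] == 1))
  # reduction with warning when distinct < L
  expect_warning(q1 <- kmeans_quantize(matrix(c(1, 2), 2, 4), n_clusters = 5),
                 "distinct")
  expect_equal(q1$n_clusters, 2L)
})

test_that("k-means quantization error is non-increasing in L", {
  set.seed(14)
  patch <- matrix(round(stats::rnorm(400, 4000, 900)), 20, 20)
  err <- vapply(1:8, function(L) {
    q <- kmeans_quantize(patch, n_clusters = L)
    sum((reconstruct_patch(q) - patch)^2)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-6))
  # agrees with stats::kmeans at its optimum for a converged case
  km <- stats::kmeans(as.numeric(patch), centers = 4, nstart = 25,
                      iter.max = 100)
  q4 <- kmeans_quantize(patch, n_clusters = 4)
  expect_equal(sum((reconstruct_patch(q4) - patch)^2), km$tot.withinss,
               tolerance = 0.02)
})

test_that("quantile quantization yields equal-count bins on a ramp", {
  ramp <- matrix(0:8191, 64, 128)
  q <- quantile_quantize(ramp, n_clusters = 4)
  expect_equal(as.numeric(table(q$labels)), rep(64 * 128 / 4, 4))
  expect_true(all(quantile_quantize(matrix(5, 3, 3), n_clusters = 1)$labels == 0))
  expect_true(all(quantile_quantize(matrix(1:9, 3, 3), n_clusters = 1)$labels == 0))
  expect_warning(quantile_quantize(matrix(7, 4, 4), n_clusters = 3), "distinct")
})

test_that("GLCM reproduces the worked 2x2 example and normalizes", {
  q <- structure(list(labels = matrix(c(0L, 1L, 0L, 1L), 2, 2),
                      centers = c(0, 1), n_clusters = 2L, method = "kmeans"),
                 class = "quantized_patch")
  # rows are [0,0] and [1,1]; horizontal pairs at distance (1,0)
  g <- compute_glcm(q, orientation_deg = 0)
  expect_equal(g$n_pairs, 2)
  expect_equal(g$probabilities,
               matrix(c(0.5, 0, 0, 0.5), 2, 2))
  f <- glcm_features(g)
  expect_equal(f$contrast, 0)
  expect_equal(f$energy, 0.5)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$correlation, 1)
  # constant-label patch: single entry 1
  qc <- structure(list(labels = matrix(1L, 4, 4), centers = c(0, 5),
                       n_clusters = 2L, method = "kmeans"),
                  class = "quantized_patch")
  gc <- compute_glcm(qc, 0)
  expect_equal(gc$probabilities[2, 2], 1)
  expect_equal(sum(gc$probabilities), 1)
  expect_error(compute_glcm(structure(list(labels = matrix(0L, 1, 1),
                                           centers = 0, n_clusters = 1L,
                                           method = "kmeans"),
                                      class = "quantized_patch"), 0),
               "smaller than|no valid")
})

test_that("GLCM mass is one for every orientation and mask pattern", {
  set.seed(77)
  for (rep in 1:10) {
    patch <- matrix(sample(0:8191, 15 * 12, replace = TRUE), 15, 12)
    mask <- matrix(stats::runif(15 * 12) < 0.8, 15, 12)
    if (sum(mask) < 6) next
    q <- suppressWarnings(kmeans_quantize(patch, mask, n_clusters = 5))
    for (th in c(0, 45, 90, 135)) {
      g <- compute_glcm(q, th)
      expect_equal(sum(g$probabilities), 1, tolerance = 1e-12)
      expect_equal(sum(g$counts), g$n_pairs)
    }
  }
})

test_that("GLCM features obey closed forms and label-shift invariances", {
  # uniform P over K^2 cells -> energy 1/K^2
  K <- 4
  gu <- structure(list(probabilities = matrix(1 / K^2, K, K),
                       counts = matrix(1, K, K), offset = c(0, 1),
                       orientation_deg = 0, n_pairs = K^2),
                  class = "glcm")
  expect_equal(glcm_features(gu)$energy, 1 / K^2)
  # diagonal-only GLCM: contrast 0, homogeneity 1
  gd <- structure(list(probabilities = diag(K) / K, counts = diag(K),
                       offset = c(0, 1), orientation_deg = 0, n_pairs = K),
                  class = "glcm")
  fd <- glcm_features(gd)
  expect_equal(fd$contrast, 0)
  expect_equal(fd$homogeneity, 1)
  # contrast invariant under adding a constant label offset (embed in larger L)
  set.seed(15)
  P <- matrix(stats::runif(9), 3, 3); P <- P / sum(P)
  g1 <- structure(list(probabilities = P), class = "glcm")
  P2 <- matrix(0, 5, 5); P2[3:5, 3:5] <- P
  g2 <- structure(list(probabilities = P2), class = "glcm")
  f1 <- glcm_features(g1); f2 <- glcm_features(g2)
  expect_equal(f1$contrast, f2$contrast)
  expect_equal(f1$correlation, f2$correlation, tolerance = 1e-12)
  expect_equal(f1$homogeneity, f2$homogeneity)
})

test_that("candidate feature extraction is deterministic and finite", {
  det <- tiny_detection(41)
  cs <- det$cs
  expect_gt(length(cs$candidates), 0)
  cd <- cs$candidates[[1]]
  f1 <- extract_features(cd)
  f2 <- extract_features(cd)
  expect_identical(f1, f2)
  expect_length(f1, 10)
  expect_true(all(is.finite(f1)))
  expect_named(f1, c("h_mean", "h_variance", "h_skewness", "h_kurtosis",
                     "h_energy", "h_entropy", "g_contrast", "g_energy",
                     "g_correlation", "g_homogeneity"))
  # a constant candidate degenerates as specified
  fake <- structure(list(id = 1L, slice_index = 1L,
                         bbox = c(r0 = 1, c0 = 1, r1 = 5, c1 = 5),
                         patch = matrix(3000, 5, 5),
                         brain_patch = matrix(TRUE, 5, 5),
                         mask = matrix(TRUE, 5, 5), area_px = 25L),
                    class = "lesion_candidate")
  ff <- suppressWarnings(extract_features(fake))
  expect_equal(unname(ff["h_energy"]), 1)
  expect_equal(unname(ff["g_contrast"]), 0)
  # whole table
  ft <- candidate_feature_table(cs)
  expect_equal(nrow(ft), length(cs$candidates))
  expect_true(all(is.finite(as.matrix(ft[wmlseg:::wml_feature_names]))))
})
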