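mask_from <- function(idx, n = 100) {
  v <- rep(FALSE, n); v[idx] <- TRUE
  binary_mask(array(v, c(n, 1, 1)))
}
all_brain <- function(n = 100) binary_mask(array(TRUE, c(n, 1, 1)))

test_that("confusion counts partition the brain", {
  b <- all_brain()
  c1 <- confusion(mask_from(1:10), mask_from(1:10), b)
  expect_equal(unclass(c1)[c("TP", "FP", "FN", "TN")],
               list(TP = 10L, FP = 0L, FN = 0L, TN = 90L))
  c2 <- confusion(mask_from(1:10), mask_from(11:20), b)
  expect_equal(unclass(c2)[c("TP", "FP", "FN", "TN")],
               list(TP = 0L, FP = 10L, FN = 10L, TN = 80L))
  c3 <- confusion(mask_from(1:2), mask_from(2:3), b)
  expect_equal(c3$TP, 1L); expect_equal(c3$FP, 1L); expect_equal(c3$FN, 1L)
  expect_equal(c1$TP + c1$FP + c1$FN + c1$TN, 100L)
  expect_error(confusion(mask_from(1, 50), mask_from(1, 100), all_brain(100)),
               "mismatch")
})

test_that("metrics reproduce the best/worst poles and a hand-worked case", {
  g <- volume_geometry(c(1, 1), 1, 0)
  perfect <- segmentation_metrics(confusion(mask_from(1:10), mask_from(1:10),
                                            all_brain()), g)
  expect_equal(perfect$DI, 1); expect_equal(perfect$JI, 1)
  expect_equal(perfect$TPR, 1); expect_equal(perfect$PPV, 1)
  expect_equal(perfect$FPR, 0); expect_equal(perfect$VD, 0)
  missed <- segmentation_metrics(confusion(mask_from(integer(0)),
                                           mask_from(1:10), all_brain()))
  expect_equal(missed$DI, 0); expect_equal(missed$TPR, 0)
  expect_equal(missed$VD, -1)
  # TP=1, FP=1, FN=1, TN=97
  m <- segmentation_metrics(confusion(mask_from(1:2), mask_from(2:3),
                                      all_brain()))
  expect_equal(m$DI, 0.5)
  expect_equal(m$JI, 1 / 3)
  expect_equal(m$PPV, 0.5)
  expect_equal(m$TPR, 0.5)
  expect_equal(m$FPR, 1 / 98)               # FP / (TP + TN) as printed
  expect_equal(m$fpr_conventional, 1 / 98)  # here TP = FP so they agree
  m2 <- segmentation_metrics(confusion(mask_from(1:4), mask_from(2:3),
                                       all_brain()))
  expect_equal(m2$FPR, 2 / (2 + 96))
  expect_equal(m2$fpr_conventional, 2 / (2 + 96))
  # undefined denominators surface as NaN / Inf, never silent zeros
  e <- segmentation_metrics(confusion(mask_from(1:3), mask_from(integer(0)),
                                      all_brain()))
  expect_true(is.nan(e$TPR))
  expect_equal(e$VD, Inf)
})

test_that("DI = 2JI/(1+JI) holds on random mask pairs", {
  set.seed(64)
  for (i in 1:200) {
    p <- mask_from(sample(100, sample(0:60, 1)))
    t <- mask_from(sample(100, sample(1:60, 1)))
    m <- segmentation_metrics(confusion(p, t, all_brain()))
    if (!is.nan(m$JI))
      expect_equal(m$DI, 2 * m$JI / (1 + m$JI), tolerance = 1e-12)
    # DI/JI symmetric under swap, PPV/TPR are not (checked by exchange)
    ms <- segmentation_metrics(confusion(t, p, all_brain()))
    expect_equal(m$DI, ms$DI)
    if (!is.nan(m$TPR) && !is.nan(ms$PPV)) expect_equal(m$TPR, ms$PPV)
  }
})

test_that("load stratification uses the stated boundaries", {
  expect_equal(stratify_load(1.6), "mild")
  expect_equal(stratify_load(5.0), "moderate")
  expect_equal(stratify_load(15.0), "moderate")
  expect_equal(stratify_load(77), "severe")
})

test_that("ICC(2,1) matches the aov mean-squares oracle", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  r <- icc_absolute_agreement(a, b)
  expect_equal(r$icc, oracle_icc21(a, b), tolerance = 1e-9)
  set.seed(17)
  for (i in 1:20) {
    x <- stats::rnorm(sample(5:30, 1), 10, 4)
    y <- x + stats::rnorm(length(x), 0, 2)
    r2 <- icc_absolute_agreement(x, y)
    expect_equal(r2$icc, oracle_icc21(x, y), tolerance = 1e-9)
    expect_true(r2$ci["lower"] <= r2$icc + 1e-9)
    expect_true(r2$ci["upper"] >= r2$icc - 1e-9)
  }
  # identical raters: perfect agreement
  expect_equal(icc_absolute_agreement(a, a)$icc, 1)
  # a large constant shift destroys absolute agreement but not Pearson r
  shifted <- icc_absolute_agreement(a, a + 50)
  expect_lt(shifted$icc, 0.2)
  expect_equal(load_correlations(a, a + 50)$pearson_r, 1)
})

test_that("correlations match textbook formulas", {
  a <- c(1.2, 3.4, 2.2, 5.6, 4.4, 8.1)
  r <- load_correlations(a, 2 * a)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  expect_equal(load_correlations(a, -a)$pearson_r, -1)
  b <- c(2, 1, 5, 4, 7, 6)
  manual_r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  rr <- load_correlations(a, b)
  expect_equal(rr$pearson_r, manual_r, tolerance = 1e-12)
  expect_equal(rr$spearman_rho,
               stats::cor(a, b, method = "spearman"), tolerance = 1e-12)
  expect_error(load_correlations(a, rep(1, 6)), "variance")
})

test_that("paired t-test with Bonferroni matches a hand-computed toy case", {
  a <- c(0.30, 0.25, 0.28, 0.35, 0.22)
  b <- c(0.24, 0.20, 0.26, 0.28, 0.21)
  d <- a - b
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  r <- paired_metric_test(a, b, n_comparisons = 4)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p_raw, p_hand, tolerance = 1e-12)
  expect_equal(r$p_bonferroni, min(1, 4 * p_hand), tolerance = 1e-12)
})
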