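#' Voxel-wise confusion counts within the brain mask
#'
#' @param pred,truth,brain congruent [binary_mask()] objects; counts are
#'   restricted to brain voxels.
#' @return List of class `confusion_counts`: `TP`, `FP`, `FN`, `TN`
#'   (summing to the brain voxel count).
#' @export
confusion <- function(pred, truth, brain) {
  stopifnot(inherits(pred, "binary_mask"), inherits(truth, "binary_mask"),
            inherits(brain, "binary_mask"))
  check_congruent(pred, truth)
  check_congruent(pred, brain)
  b <- brain$voxels
  p <- pred$voxels[b]
  t <- truth$voxels[b]
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

#' Segmentation quality metrics
#'
#' The six standard voxel-wise metrics: Dice index
#' `DI = 2TP / (2TP + FP + FN)`, Jaccard index `JI = TP / (TP + FP + FN)`,
#' true positive rate `TP / (TP + FN)`, false positive rate implemented
#' as printed in the source convention, `FPR = FP / (TP + TN)`
#' (the conventional `FP / (FP + TN)` is reported separately as
#' `fpr_conventional`), positive predictive value `TP / (TP + FP)`, and
#' the signed volume difference `VD = (Vol(auto) - Vol(GT)) / Vol(GT)`.
#' Undefined denominators yield `NaN` (or `+Inf` for VD with an empty
#' ground truth and non-empty prediction), never a silent 0.
#'
#' @param counts a `confusion_counts`.
#' @param geometry optional [volume_geometry()]; when given, `vol_auto_ml`,
#'   `vol_gt_ml` and `load_group` are included.
#' @return Named list of metrics.
#' @export
segmentation_metrics <- function(counts, geometry = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  safe <- function(num, den) if (den > 0) num / den else NaN
  vd <- if (TP + FN > 0) {
    ((TP + FP) - (TP + FN)) / (TP + FN)
  } else if (TP + FP > 0) Inf else NaN
  out <- list(
    DI = safe(2 * TP, 2 * TP + FP + FN),
    JI = safe(TP, TP + FP + FN),
    TPR = safe(TP, TP + FN),
    FPR = safe(FP, TP + TN),
    fpr_conventional = safe(FP, FP + TN),
    PPV = safe(TP, TP + FP),
    VD = vd)
  if (!is.null(geometry)) {
    vx <- voxel_volume_mm3(geometry) / 1000
    out$vol_auto_ml <- (TP + FP) * vx
    out$vol_gt_ml <- (TP + FN) * vx
    out$load_group <- stratify_load(out$vol_gt_ml)
  }
  out
}

#' Evaluate a predicted mask against ground truth
#'
#' @inheritParams confusion
#' @param geometry a [volume_geometry()] for the volumetrics.
#' @return List of class `evaluation_report`: the confusion counts plus
#'   everything from [segmentation_metrics()].
#' @export
evaluate_segmentation <- function(pred, truth, brain, geometry) {
  counts <- confusion(pred, truth, brain)
  structure(c(list(counts = counts), segmentation_metrics(counts, geometry)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: DI %.3f, JI %.3f, TPR %.3f, FPR %.3f, PPV %.3f, VD %+.3f\n",
              x$DI, x$JI, x$TPR, x$FPR, x$PPV, x$VD))
  if (!is.null(x$vol_gt_ml))
    cat(sprintf("  volumes: auto %.3f mL vs GT %.3f mL (%s load)\n",
                x$vol_auto_ml, x$vol_gt_ml, x$load_group))
  invisible(x)
}

#' Lesion-load stratum of a ground-truth volume
#'
#' Mild below 5 mL, moderate 5--15 mL (both boundaries inclusive),
#' severe above 15 mL.
#'
#' @param gt_volume_ml non-negative volume in mL.
#' @return `"mild"`, `"moderate"` or `"severe"`.
#' @export
stratify_load <- function(gt_volume_ml) {
  stopifnot(gt_volume_ml >= 0)
  if (gt_volume_ml < 5) "mild"
  else if (gt_volume_ml <= 15) "moderate"
  else "severe"
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-measure ICC(2,1) from the two-way ANOVA mean squares of an
#' n-subject by k-rater table, with the F-based 95 % confidence interval.
#' Sensitive to systematic rater offsets (unlike Pearson correlation),
#' which is why it is the agreement statistic for automated vs manual
#' lesion loads.
#'
#' @param rater_a,rater_b numeric vectors of paired measurements
#'   (e.g. automated and manual lesion volumes), length at least 3.
#' @param conf_level confidence level for the interval.
#' @return List: `icc`, `ci` (length-2), `ms` (mean squares), `n`, `k`.
#' @export
icc_absolute_agreement <- function(rater_a, rater_b, conf_level = 0.95) {
  stopifnot(length(rater_a) == length(rater_b), length(rater_a) >= 3)
  x <- cbind(rater_a, rater_b)
  n <- nrow(x); k <- ncol(x)
  if (stats::var(rater_a) == 0 && stats::var(rater_b) == 0)
    stop("icc_absolute_agreement: zero variance in both raters")
  grand <- mean(x)
  row_means <- rowMeans(x); col_means <- colMeans(x)
  SSR <- k * sum((row_means - grand)^2)
  SSC <- n * sum((col_means - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  # F-based CI (McGraw & Wong A-1 form)
  alpha <- 1 - conf_level
  Fj <- MSC / MSE
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  F_star_u <- stats::qf(1 - alpha / 2, n - 1, v)
  F_star_l <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - F_star_u * MSE) /
    (F_star_u * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (F_star_l * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F_star_l * MSR)
  list(icc = icc, ci = c(lower = lower, upper = upper),
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE), n = n, k = k)
}

#' Pearson and Spearman correlation of paired lesion loads
#'
#' @param a,b numeric vectors, length at least 3.
#' @return List: `pearson_r`, `pearson_p` (t-based, two-sided),
#'   `spearman_rho`.
#' @export
load_correlations <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("load_correlations: zero variance input")
  ct <- stats::cor.test(a, b, method = "pearson")
  rho <- stats::cor(rank(a), rank(b))  # average ranks on ties
  list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
       spearman_rho = rho)
}

#' Paired t-test with Bonferroni correction
#'
#' Compares a metric between two methods over the same subjects; the
#' p-value is multiplied by `n_comparisons` (capped at 1), matching a
#' Bonferroni correction over a family of metric comparisons.
#'
#' @param a,b paired metric values per subject.
#' @param n_comparisons size of the comparison family (default 4).
#' @return List: `t`, `df`, `p_raw`, `p_bonferroni`.
#' @export
paired_metric_test <- function(a, b, n_comparisons = 4L) {
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value,
       p_bonferroni = min(1, tt$p.value * n_comparisons))
}
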