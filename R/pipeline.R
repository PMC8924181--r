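#' Train the full segmentation pipeline on a labeled cohort
#'
#' Fits everything the segmentation stage needs: the cohort-wide standard
#' intensity scale, the random-forest false-positive filter (trained on
#' ground-truth-labeled candidates), and the LOF lesion-intensity
#' reference model built from the standardized intensities of the
#' training lesions' ground-truth voxels.
#'
#' @param cohort list of `phantom_bundle` (or any list with elements
#'   `flair`, `brain`, `gt_lesions`).
#' @param n_trees,max_depth forest operating point (default T=25, D=25).
#' @param min_pts,lof_threshold LOF neighbourhood size and inlier cutoff.
#' @param trim_fraction,k_extreme,min_area,margin_px detection parameters.
#' @param max_reference LOF reference size after downsampling.
#' @param imbalance_ratio passed to [generate_training_set()]; `NULL`
#'   (default) trains on every detected candidate.
#' @param seed seed for forest training and reference downsampling.
#' @return Object of class `wml_pipeline_model`.
#' @export
train_wml_pipeline <- function(cohort, n_trees = 25L, max_depth = 25L,
                               min_pts = 20L, lof_threshold = 1.5,
                               trim_fraction = 0.2, k_extreme = 3,
                               min_area = 3L, margin_px = 2L,
                               max_reference = 10000L,
                               imbalance_ratio = NULL, seed = 1L) {
  ts <- generate_training_set(cohort, imbalance_ratio = imbalance_ratio,
                              seed = seed,
                              trim_fraction = trim_fraction,
                              k_extreme = k_extreme, min_area = min_area,
                              margin_px = margin_px)
  std <- attr(ts, "standard_landmarks")
  rf <- train_classifier(ts, n_trees = n_trees, max_depth = max_depth,
                         seed = seed)
  ref <- unlist(lapply(cohort, function(b) {
    sv <- standardize(b$flair, fit_landmark_map(b$flair, b$brain,
                                                target_landmarks = std))
    as.numeric(sv$voxels[b$gt_lesions$voxels])
  }))
  if (length(ref) < min_pts + 1)
    stop("train_wml_pipeline: too few ground-truth lesion voxels for LOF")
  lof <- fit_lof_model(ref, min_pts = min_pts, threshold = lof_threshold,
                       max_reference = max_reference, seed = seed)
  structure(list(standard_landmarks = std, rf = rf, lof = lof,
                 params = list(trim_fraction = trim_fraction,
                               k_extreme = k_extreme, min_area = min_area,
                               margin_px = margin_px),
                 seed = seed),
            class = "wml_pipeline_model")
}

#' @export
print.wml_pipeline_model <- function(x, ...) {
  cat("wml_pipeline_model:\n")
  cat(sprintf("  forest: %d trees, depth <= %d\n", x$rf$n_trees, x$rf$max_depth))
  print(x$lof)
  invisible(x)
}

#' Segment white matter lesions in a FLAIR volume
#'
#' The full inference chain: standardize against the model's cohort
#' scale, detect hyperintense candidates per slice (trimmed-mean boxplot
#' extreme fence), classify each candidate's 10-feature vector with the
#' random forest, and refine the surviving candidates' boundaries with
#' the LOF intensity model, restricted to the slice's outer-fence
#' hyperintense zone. Candidates whose refinement is empty are dropped.
#'
#' @param volume a [gray_volume()] FLAIR stack (native intensities).
#' @param brain a [binary_mask()].
#' @param model a `wml_pipeline_model`.
#' @return List of class `wml_segmentation`: `mask` (final
#'   [binary_mask()]), `tmod_mask` (candidate union before
#'   classification/refinement), `candidates` (`candidate_set`), `scores`
#'   (per-candidate classification), `standardized` (the standardized
#'   volume), `kept` (ids of candidates surviving classification).
#' @export
wml_segment <- function(volume, brain, model) {
  stopifnot(inherits(model, "wml_pipeline_model"))
  p <- model$params
  sv <- standardize(volume, fit_landmark_map(
    volume, brain, target_landmarks = model$standard_landmarks))
  cs <- detect_candidates(sv, brain, trim_fraction = p$trim_fraction,
                          k_extreme = p$k_extreme, min_area = p$min_area,
                          margin_px = p$margin_px)
  d <- dim(sv$voxels)
  final <- array(FALSE, d)
  scores <- NULL
  kept <- integer(0)
  if (length(cs$candidates)) {
    ft <- candidate_feature_table(cs)
    scores <- cbind(ft["id"], classify_candidates(model$rf,
                                                  ft[wml_feature_names]))
    for (i in seq_along(cs$candidates)) {
      if (scores$label[i] != "WML") next
      cd <- cs$candidates[[i]]
      rb <- refine_boundary(cd, model$lof)
      # half-maximum boundary zone: halfway between the local
      # normal-brain level (non-component patch voxels; falls back to the
      # slice trimmed mean) and the candidate peak (FWHM criterion)
      ring <- cd$brain_patch & !cd$mask
      bg <- if (any(ring)) stats::median(cd$patch[ring])
            else cs$thresholds$trimmed_mean[cd$slice_index]
      peak <- max(cd$patch[cd$mask])
      zone <- cd$patch > (bg + peak) / 2
      refined <- rb$refined_mask & zone
      if (!any(refined)) next
      kept <- c(kept, cd$id)
      b <- cd$bbox
      sl <- final[b["r0"]:b["r1"], b["c0"]:b["c1"], cd$slice_index]
      final[b["r0"]:b["r1"], b["c0"]:b["c1"], cd$slice_index] <- sl | refined
    }
  }
  structure(list(mask = binary_mask(final), tmod_mask = cs$mask,
                 candidates = cs, scores = scores, standardized = sv,
                 kept = kept),
            class = "wml_segmentation")
}

#' @export
print.wml_segmentation <- function(x, ...) {
  cat(sprintf("wml_segmentation: %d candidates -> %d kept, %d voxels final (%d before refinement)\n",
              length(x$candidates$candidates), length(x$kept),
              sum(x$mask$voxels), sum(x$tmod_mask$voxels)))
  invisible(x)
}

#' End-to-end synthetic benchmark
#'
#' Generates disjoint seeded train and test cohorts of mild-load
#' phantoms, trains the pipeline on the training cohort, segments every
#' test phantom, and reports candidate-level classifier accuracy on the
#' held-out phantoms, voxel-level false-positive counts before (TMOD
#' candidate stage) and after classification + LOF refinement, Table-style
#' per-phantom metrics, and volume agreement statistics (ICC(2,1),
#' Pearson, Spearman) between automated and ground-truth loads.
#'
#' @param n_train,n_test cohort sizes (default 10 / 10).
#' @param seed master seed; the test cohort derives from `seed + 500000`.
#' @param load_profile stratum of both cohorts (default `"mild"`).
#' @param ... overrides for [train_wml_pipeline()].
#' @return List: `model`, `per_phantom` (data.frame with DI, JI, TPR,
#'   FPR, PPV, VD, loads and FP counts), `rf_holdout_accuracy`,
#'   `mean_dice`, `median_abs_vd`, `fp_before`, `fp_after`, `agreement`
#'   (ICC + correlations).
#' @export
phantom_benchmark <- function(n_train = 10L, n_test = 10L, seed = 1L,
                              load_profile = "mild", ...) {
  train <- generate_cohort(n_train, load_profile, seed = seed)
  test <- generate_cohort(n_test, load_profile, seed = seed + 500000L)
  model <- train_wml_pipeline(train, seed = seed, ...)
  rows <- list()
  n_correct <- 0L; n_cand <- 0L
  for (i in seq_along(test)) {
    b <- test[[i]]
    seg <- wml_segment(b$flair, b$brain, model)
    rep_full <- evaluate_segmentation(seg$mask, b$gt_lesions, b$brain,
                                      b$flair$geometry)
    rep_tmod <- confusion(seg$tmod_mask, b$gt_lesions, b$brain)
    if (!is.null(seg$scores)) {
      truth <- label_candidates(seg$candidates, b$gt_lesions)
      n_correct <- n_correct + sum(seg$scores$label == truth)
      n_cand <- n_cand + length(truth)
    }
    rows[[i]] <- data.frame(
      phantom = i, DI = rep_full$DI, JI = rep_full$JI, TPR = rep_full$TPR,
      FPR = rep_full$FPR, PPV = rep_full$PPV, VD = rep_full$VD,
      vol_auto_ml = rep_full$vol_auto_ml, vol_gt_ml = rep_full$vol_gt_ml,
      fp_before = rep_tmod$FP, fp_after = rep_full$counts$FP)
  }
  per <- do.call(rbind, rows)
  agreement <- c(
    icc = list(icc_absolute_agreement(per$vol_auto_ml, per$vol_gt_ml)),
    load_correlations(per$vol_auto_ml, per$vol_gt_ml))
  list(model = model, per_phantom = per,
       rf_holdout_accuracy = n_correct / n_cand,
       mean_dice = mean(per$DI),
       median_abs_vd = stats::median(abs(per$VD)),
       fp_before = per$fp_before, fp_after = per$fp_after,
       agreement = agreement)
}
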