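wml_feature_names <- c("h_mean", "h_variance", "h_skewness", "h_kurtosis",
                       "h_energy", "h_entropy", "g_contrast", "g_energy",
                       "g_correlation", "g_homogeneity")

#' Label detected candidates against a ground-truth lesion mask
#'
#' A candidate is a true WML when its component mask overlaps the ground
#' truth on its slice; under the default `overlap_rule = 0` any positive
#' overlap counts, otherwise the overlapping fraction of the candidate
#' area must reach `overlap_rule`.
#'
#' @param candidate_set a `candidate_set` from [detect_candidates()].
#' @param gt_mask ground-truth [binary_mask()] congruent with the volume
#'   the candidates came from.
#' @param overlap_rule minimum overlap fraction; 0 means any overlap.
#' @return Factor vector (`"non-WML"`, `"WML"`), one per candidate.
#' @export
label_candidates <- function(candidate_set, gt_mask, overlap_rule = 0) {
  stopifnot(inherits(candidate_set, "candidate_set"),
            inherits(gt_mask, "binary_mask"))
  labs <- vapply(candidate_set$candidates, function(cd) {
    b <- cd$bbox
    gt <- gt_mask$voxels[b["r0"]:b["r1"], b["c0"]:b["c1"], cd$slice_index]
    ov <- sum(gt & cd$mask)
    if (overlap_rule <= 0) ov > 0 else (ov / cd$area_px) >= overlap_rule
  }, logical(1))
  factor(ifelse(labs, "WML", "non-WML"), levels = c("non-WML", "WML"))
}

#' Assemble a training set from candidates and ground truth
#'
#' Extracts the 10-scalar feature vector of every candidate and labels it
#' by ground-truth overlap (see [label_candidates()]).
#'
#' @inheritParams label_candidates
#' @param ... feature-extraction parameters for [extract_features()].
#' @return Object of class `training_set`: `features` (data.frame),
#'   `labels` (factor), `provenance` (candidate ids).
#' @export
build_training_set <- function(candidate_set, gt_mask, overlap_rule = 0,
                               ...) {
  if (!length(candidate_set$candidates))
    stop("build_training_set: no candidates")
  ft <- candidate_feature_table(candidate_set, ...)
  labels <- label_candidates(candidate_set, gt_mask, overlap_rule)
  training_set(ft[wml_feature_names], labels, ft$id)
}

#' @rdname build_training_set
#' @param features data.frame of the 10 feature columns.
#' @param labels factor with levels `non-WML`, `WML`.
#' @param provenance candidate ids.
#' @export
training_set <- function(features, labels, provenance = seq_len(nrow(features))) {
  features <- as.data.frame(features)[wml_feature_names]
  labels <- factor(labels, levels = c("non-WML", "WML"))
  stopifnot(nrow(features) == length(labels),
            all(is.finite(as.matrix(features))))
  structure(list(features = features, labels = labels,
                 provenance = provenance), class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d samples (%s)\n", length(x$labels),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Train the random-forest false-positive filter
#'
#' Forest of `n_trees` trees with depth at most `max_depth` (operating
#' point T = 25, D = 25), Gini splits, `ceiling(sqrt(p))` candidate
#' features per split, bootstrap sampling seeded by `seed`. No class
#' rebalancing by default; pass `class_weights` to enable it.
#'
#' @param ts a `training_set`.
#' @param n_trees,max_depth forest size and depth cap.
#' @param seed RNG seed making training reproducible.
#' @param decision_threshold vote fraction above which a candidate is
#'   called WML.
#' @param class_weights optional named weights for `non-WML` / `WML`.
#' @return Object of class `wml_rf_model`.
#' @export
train_classifier <- function(ts, n_trees = 25L, max_depth = 25L, seed = 1L,
                             decision_threshold = 0.5,
                             class_weights = NULL) {
  # threshold > 1 is allowed deliberately: it classifies nothing as WML
  stopifnot(inherits(ts, "training_set"),
            n_trees >= 1, max_depth >= 1, decision_threshold > 0)
  if (nlevels(droplevels(ts$labels)) < 2)
    stop("train_classifier: both classes must be present")
  dat <- cbind(ts$features, .label = ts$labels)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = n_trees, max.depth = max_depth,
    mtry = ceiling(sqrt(length(wml_feature_names))),
    splitrule = "gini", probability = TRUE,
    class.weights = if (is.null(class_weights)) NULL
                    else class_weights[levels(ts$labels)],
    seed = seed, num.threads = 1)
  structure(list(forest = fit, feature_names = wml_feature_names,
                 n_trees = n_trees, max_depth = max_depth, seed = seed,
                 decision_threshold = decision_threshold),
            class = "wml_rf_model")
}

#' Classify candidate feature vectors
#'
#' @param model a `wml_rf_model`.
#' @param features data.frame (or named vector) of the 10 features; the
#'   column set must match the model's feature contract.
#' @return data.frame with `score` (forest vote fraction for WML) and
#'   `label` (factor by `decision_threshold`, `score >= threshold` is WML).
#' @export
classify_candidates <- function(model, features) {
  stopifnot(inherits(model, "wml_rf_model"))
  if (is.numeric(features) && !is.null(names(features)))
    features <- as.data.frame(t(features))
  if (!all(model$feature_names %in% colnames(features)))
    stop("classify_candidates: feature columns do not match the model contract")
  features <- as.data.frame(features)[model$feature_names]
  pr <- stats::predict(model$forest, data = features,
                       num.threads = 1)$predictions
  score <- pr[, "WML"]
  data.frame(score = score,
             label = factor(ifelse(score >= model$decision_threshold,
                                   "WML", "non-WML"),
                            levels = c("non-WML", "WML")))
}

#' Seeded stratified fold assignment
#'
#' @param labels factor of class labels.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per sample; within each class the ids are
#'   balanced to within one sample.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  stopifnot(n_folds >= 2)
  folds <- integer(length(labels))
  set.seed(seed)
  for (lv in levels(factor(labels))) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Tenfold stratified cross-validation over feature parameters
#'
#' For each grid point (cluster count, GLCM orientation, quantizer) the
#' features of every candidate are re-extracted with those parameters and
#' a forest is evaluated by stratified k-fold cross-validation; the mean
#' fold accuracy is reported per grid point.
#'
#' @param candidates list of `lesion_candidate` (or a `candidate_set`).
#' @param labels factor parallel to `candidates`.
#' @param grid data.frame with columns among `n_clusters`,
#'   `orientation_deg`, `quantizer`.
#' @param n_folds,n_trees,max_depth,seed harness parameters.
#' @return `grid` with an appended `mean_accuracy` column.
#' @export
cross_validate <- function(candidates, labels,
                           grid = expand.grid(n_clusters = 1:7,
                                              orientation_deg = 0,
                                              quantizer = "kmeans",
                                              stringsAsFactors = FALSE),
                           n_folds = 10L, n_trees = 25L, max_depth = 25L,
                           seed = 1L) {
  if (inherits(candidates, "candidate_set")) candidates <- candidates$candidates
  labels <- factor(labels, levels = c("non-WML", "WML"))
  stopifnot(length(candidates) == length(labels))
  folds <- stratified_folds(labels, n_folds, seed)
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    ft <- candidate_feature_table(
      candidates,
      n_clusters = grid$n_clusters[gi] %||% 5L,
      orientation_deg = grid$orientation_deg[gi] %||% 0,
      quantizer = as.character(grid$quantizer[gi] %||% "kmeans"))
    X <- ft[wml_feature_names]
    fold_acc <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(labels[tr])) < 2)
        stop("cross_validate: training fold with a single class")
      ts <- training_set(X[tr, , drop = FALSE], labels[tr])
      m <- train_classifier(ts, n_trees, max_depth, seed = seed)
      pred <- classify_candidates(m, X[!tr, , drop = FALSE])
      mean(pred$label == labels[!tr])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  cbind(grid, mean_accuracy = acc)
}

#' Persist / restore a trained model
#'
#' Serialization round-trips exactly: a reloaded model produces identical
#' predictions.
#'
#' @param model a `wml_rf_model` (or full `wml_pipeline_model`).
#' @param path destination `.rds` path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
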