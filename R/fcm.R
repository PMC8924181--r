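#' Fuzzy C-means tissue segmentation (WM / GM / CSF)
#'
#' Standard fuzzy C-means clustering of scalar brain-voxel intensities.
#' Because the feature is one-dimensional, voxels are aggregated by unique
#' intensity (with counts as weights), which is exact and makes the
#' iteration cost independent of volume size. Final class centers are
#' sorted ascending and labeled CSF < GM < WM by intensity.
#'
#' @param volume a standardized [gray_volume()].
#' @param brain a [binary_mask()].
#' @param n_classes number of tissue classes (default 3).
#' @param fuzzifier fuzziness exponent m > 1 (default 2).
#' @param tol convergence threshold on the maximum center shift.
#' @param max_iter iteration cap.
#' @param init `"percentile"` (deterministic, centers at equally spaced
#'   masked-intensity percentiles between p10 and p90) or `"random"`.
#' @param seed RNG seed, used only for `init = "random"`.
#' @return An object of class `tissue_map`: `memberships` (matrix, one row
#'   per brain voxel, columns in center order), `hard_labels` (integer
#'   array, 0 outside brain, 1..n_classes = argmax membership),
#'   `class_centers` (ascending), `objective` (per-iteration trajectory),
#'   `brain_index` (linear indices of brain voxels).
#' @export
fcm_tissue_segmentation <- function(volume, brain, n_classes = 3L,
                                    fuzzifier = 2, tol = 1e-5,
                                    max_iter = 300L,
                                    init = c("percentile", "random"),
                                    seed = NULL) {
  stopifnot(inherits(volume, "gray_volume"), inherits(brain, "binary_mask"),
            n_classes >= 2, fuzzifier > 1)
  check_congruent(volume, brain)
  init <- match.arg(init)
  idx <- which(brain$voxels)
  if (!length(idx)) stop("fcm_tissue_segmentation: empty brain mask")
  x_all <- as.numeric(volume$voxels[idx])
  tab <- table(x_all)
  x <- as.numeric(names(tab))
  w <- as.numeric(tab)
  if (length(x) < n_classes)
    stop("fcm_tissue_segmentation: fewer distinct intensities (", length(x),
         ") than classes (", n_classes, ")")

  centers <- if (init == "percentile") {
    unname(stats::quantile(x_all, seq(0.10, 0.90, length.out = n_classes),
                           type = 7))
  } else {
    if (!is.null(seed)) set.seed(seed)
    sort(sample(x, n_classes))
  }
  # tied initial centers can arise from skewed histograms; nudge apart
  centers <- centers + seq(0, 1e-6, length.out = n_classes)

  p <- 2 / (fuzzifier - 1)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    u <- fcm_memberships(d2, p)
    um <- u^fuzzifier
    objective <- c(objective, sum(w * rowSums(um * d2)))
    new_centers <- colSums(w * um * x) / colSums(w * um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  ord <- order(centers)
  centers <- centers[ord]

  d2v <- outer(x_all, centers, function(a, b) (a - b)^2)
  uv <- fcm_memberships(d2v, p)
  hard <- array(0L, dim(volume$voxels))
  hard[idx] <- max.col(uv, ties.method = "first")
  structure(list(memberships = uv, hard_labels = hard,
                 class_centers = centers, objective = objective,
                 brain_index = idx, n_iter = length(objective)),
            class = "tissue_map")
}

# u_jk = (sum_l (d_jk/d_jl)^(1/(m-1)))^-1 on squared distances; a voxel
# coinciding with a center gets full membership there
fcm_memberships <- function(d2, p) {
  inv <- d2^(-p / 2)
  zero <- !is.finite(inv)
  if (any(zero)) {
    rows <- which(rowSums(zero) > 0)
    inv[rows, ] <- 0
    inv[zero] <- 1
  }
  inv / rowSums(inv)
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf("tissue_map: %d classes, centers %s, %d iterations\n",
              length(x$class_centers),
              paste(round(x$class_centers, 1), collapse = " / "),
              x$n_iter))
  invisible(x)
}
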