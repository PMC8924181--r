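#' Fit a percentile-landmark intensity map
#'
#' Piecewise-linear landmark standardization in the Nyul-Udupa style: the
#' source landmarks are percentiles of the brain-masked intensity
#' distribution (default p1, deciles p10..p90, p99) and are mapped onto
#' fixed positions of a standardized scale `[0, target_levels - 1]`.
#'
#' When `target_landmarks` is `NULL` the targets are the anchored affine
#' image of the source landmarks: p1 maps to 0, the last landmark to
#' `(1 - headroom) * (target_levels - 1)`, intermediate landmarks
#' proportionally. The headroom keeps resolution for intensities above the
#' top landmark (lesions live there) before clipping. A cohort-wide
#' standard scale from [fit_standard_scale()] can be passed instead, which
#' is what the pipeline does.
#'
#' @param volume a [gray_volume()].
#' @param brain a [binary_mask()] selecting brain voxels.
#' @param percentiles increasing percentiles in (0, 100).
#' @param target_levels standardized level count L (default 8192).
#' @param target_landmarks optional explicit target positions.
#' @param headroom fraction of the standardized scale reserved above the
#'   top landmark (default 0.15).
#' @return An object of class `landmark_map` with elements
#'   `source_landmarks`, `target_landmarks`, `target_levels`.
#' @export
fit_landmark_map <- function(volume, brain,
                             percentiles = c(1, seq(10, 90, by = 10), 99),
                             target_levels = 8192L,
                             target_landmarks = NULL,
                             headroom = 0.15) {
  stopifnot(inherits(volume, "gray_volume"), inherits(brain, "binary_mask"))
  check_congruent(volume, brain)
  stopifnot(all(percentiles > 0), all(percentiles < 100),
            all(diff(percentiles) > 0), length(percentiles) >= 2)
  x <- as.numeric(volume$voxels[brain$voxels])
  if (!length(x)) stop("fit_landmark_map: empty brain mask")
  if (max(x) == min(x))
    stop("fit_landmark_map: constant brain region, no dynamic range")
  src <- unname(stats::quantile(x, percentiles / 100, type = 7))
  if (is.null(target_landmarks)) {
    target_landmarks <- (src - src[1]) / (src[length(src)] - src[1]) *
      (1 - headroom) * (target_levels - 1)
  }
  stopifnot(length(target_landmarks) == length(src))
  # collapse degenerate (tied) adjacent source landmarks
  keep <- c(TRUE, diff(src) > 0)
  if (!all(keep)) {
    warning("fit_landmark_map: collapsing ", sum(!keep),
            " degenerate landmark(s)")
    src <- src[keep]
    target_landmarks <- target_landmarks[keep]
  }
  if (any(diff(target_landmarks) <= 0))
    stop("fit_landmark_map: target landmarks must be strictly increasing")
  structure(list(source_landmarks = src,
                 target_landmarks = as.numeric(target_landmarks),
                 percentiles = percentiles[keep],
                 target_levels = as.integer(target_levels)),
            class = "landmark_map")
}

#' Fit a cohort-wide standard intensity scale
#'
#' Maps each training volume's landmarks onto the anchored scale (first
#' landmark at 0, last at `(1 - headroom) * (target_levels - 1)`) and
#' averages the mapped positions across volumes. The result is the
#' `target_landmarks` vector every volume of a study is standardized
#' against, so tissue classes land at comparable gray levels across scans.
#'
#' @param volumes list of [gray_volume()].
#' @param brains list of [binary_mask()], parallel to `volumes`.
#' @inheritParams fit_landmark_map
#' @return Numeric vector of standard target landmarks.
#' @export
fit_standard_scale <- function(volumes, brains,
                               percentiles = c(1, seq(10, 90, by = 10), 99),
                               target_levels = 8192L, headroom = 0.15) {
  stopifnot(length(volumes) == length(brains), length(volumes) >= 1)
  span <- (1 - headroom) * (target_levels - 1)
  mapped <- vapply(seq_along(volumes), function(i) {
    x <- as.numeric(volumes[[i]]$voxels[brains[[i]]$voxels])
    q <- unname(stats::quantile(x, percentiles / 100, type = 7))
    (q - q[1]) / (q[length(q)] - q[1]) * span
  }, numeric(length(percentiles)))
  rowMeans(mapped)
}

#' Standardize a volume through a fitted landmark map
#'
#' Applies piecewise-linear interpolation between landmark pairs; beyond the
#' terminal landmarks the terminal segment's slope is extrapolated; the
#' result is clipped to `[0, target_levels - 1]` and rounded to integers.
#' The map is monotone non-decreasing in the input intensity.
#'
#' @param volume a [gray_volume()].
#' @param map a `landmark_map` from [fit_landmark_map()].
#' @return A [gray_volume()] on the standardized scale
#'   (`scale_max = target_levels - 1`), with attribute `standardized = TRUE`.
#' @export
standardize <- function(volume, map) {
  stopifnot(inherits(volume, "gray_volume"), inherits(map, "landmark_map"))
  out <- piecewise_linear(as.numeric(volume$voxels),
                          map$source_landmarks, map$target_landmarks)
  out <- pmin(pmax(round(out), 0), map$target_levels - 1L)
  sv <- gray_volume(array(out, dim(volume$voxels)), volume$geometry,
                    scale_max = map$target_levels - 1L)
  attr(sv, "standardized") <- TRUE
  sv
}

# piecewise-linear with terminal-slope extrapolation (not constant clamping)
piecewise_linear <- function(x, xs, ys) {
  n <- length(xs)
  idx <- findInterval(x, xs, all.inside = TRUE)  # segment index 1..n-1
  x0 <- xs[idx]; x1 <- xs[idx + 1L]
  y0 <- ys[idx]; y1 <- ys[idx + 1L]
  y0 + (x - x0) / (x1 - x0) * (y1 - y0)
}
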