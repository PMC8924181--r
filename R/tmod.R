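#' Trimmed mean
#'
#' Mean after discarding the lowest and highest `trim_fraction` of the
#' sorted values; the count trimmed per tail is `floor(n * trim_fraction)`.
#' Used to estimate the normal-brain intensity level per slice without
#' lesion contamination.
#'
#' @param values numeric vector.
#' @param trim_fraction fraction in `[0, 0.5)` trimmed from each tail.
#' @return The trimmed mean.
#' @examples
#' trimmed_mean(1:10, 0.2)  # mean of 3..8 = 5.5
#' @export
trimmed_mean <- function(values, trim_fraction = 0.2) {
  stopifnot(is.numeric(values), trim_fraction >= 0, trim_fraction < 0.5)
  if (!length(values)) stop("trimmed_mean: empty input")
  mean(trimmed_values(values, trim_fraction))
}

trimmed_values <- function(values, trim_fraction) {
  n <- length(values)
  k <- floor(n * trim_fraction)
  if (k == 0) return(values)
  sort(values)[(k + 1):(n - k)]
}

#' Per-slice boxplot threshold for hyperintense outliers
#'
#' Computes quartiles of the trimmed, brain-masked intensity distribution
#' of one axial slice and places the extreme-outlier fence at
#' `q3 + k_extreme * IQR` (Tukey's extreme fence at the default
#' `k_extreme = 3`). Voxels strictly above the fence are lesion candidates;
#' `has_wml` records whether any exist in the slice.
#'
#' @param slice numeric matrix of standardized intensities.
#' @param brain logical matrix selecting brain pixels.
#' @param trim_fraction tail fraction removed before the boxplot.
#' @param k_extreme fence multiplier on the interquartile range.
#' @return A list of class `slice_threshold`: `trimmed_mean`, `q1`, `q3`,
#'   `iqr`, `extreme_threshold`, `has_wml`.
#' @export
slice_threshold <- function(slice, brain, trim_fraction = 0.2,
                            k_extreme = 3) {
  stopifnot(is.matrix(slice), is.matrix(brain), identical(dim(slice), dim(brain)))
  x <- as.numeric(slice[brain])
  if (!length(x)) stop("slice_threshold: empty brain region")
  xt <- trimmed_values(x, trim_fraction)
  q <- unname(stats::quantile(xt, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  fence <- q[2] + k_extreme * iqr
  structure(list(trimmed_mean = mean(xt), q1 = q[1], q3 = q[2], iqr = iqr,
                 extreme_threshold = fence,
                 has_wml = any(x > fence)),
            class = "slice_threshold")
}

#' Detect lesion candidates in a standardized volume
#'
#' Per slice: intensities above the slice's extreme-outlier fence form a
#' binary map; its 8-connected components of at least `min_area` pixels
#' become candidates. Each candidate carries its bounding box dilated by
#' `margin_px` (clipped to the slice), the standardized-intensity patch
#' over that box, and the component mask within the patch. Ids are
#' assigned slice-major, then by top-left corner.
#'
#' @param volume standardized [gray_volume()].
#' @param brain [binary_mask()].
#' @param trim_fraction,k_extreme see [slice_threshold()].
#' @param min_area minimum component area in pixels (default 3).
#' @param margin_px patch margin around the bounding box (default 2).
#' @return A list of class `candidate_set`: `candidates` (list of
#'   `lesion_candidate`), `mask` ([binary_mask()] union of all retained
#'   components), `thresholds` (data frame of per-slice statistics).
#' @export
detect_candidates <- function(volume, brain, trim_fraction = 0.2,
                              k_extreme = 3, min_area = 3L,
                              margin_px = 2L) {
  stopifnot(inherits(volume, "gray_volume"), inherits(brain, "binary_mask"))
  check_congruent(volume, brain)
  d <- dim(volume$voxels)
  union <- array(FALSE, d)
  cands <- list()
  thr_rows <- vector("list", d[3])
  next_id <- 1L
  for (s in seq_len(d[3])) {
    sl <- volume$voxels[, , s]
    br <- brain$voxels[, , s]
    if (!any(br)) {
      thr_rows[[s]] <- data.frame(slice = s, trimmed_mean = NA_real_,
                                  q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                                  extreme_threshold = NA_real_, has_wml = FALSE)
      next
    }
    th <- slice_threshold(sl, br, trim_fraction, k_extreme)
    thr_rows[[s]] <- data.frame(slice = s, trimmed_mean = th$trimmed_mean,
                                q1 = th$q1, q3 = th$q3, iqr = th$iqr,
                                extreme_threshold = th$extreme_threshold,
                                has_wml = th$has_wml)
    above <- br & (sl > th$extreme_threshold)
    if (!any(above)) next
    labels <- label_components_8(above)
    comp_ids <- seq_len(max(labels))
    areas <- tabulate(labels[labels > 0], nbins = max(labels))
    keep <- comp_ids[areas >= min_area]
    # order by top-left corner (row-major) of the bounding box
    if (length(keep)) {
      corners <- t(vapply(keep, function(k) {
        w <- which(labels == k, arr.ind = TRUE)
        c(min(w[, 1]), min(w[, 2]))
      }, numeric(2)))
      keep <- keep[order(corners[, 1], corners[, 2])]
    }
    for (k in keep) {
      w <- which(labels == k, arr.ind = TRUE)
      r0 <- max(1L, min(w[, 1]) - margin_px)
      r1 <- min(d[1], max(w[, 1]) + margin_px)
      c0 <- max(1L, min(w[, 2]) - margin_px)
      c1 <- min(d[2], max(w[, 2]) + margin_px)
      comp <- labels[r0:r1, c0:c1] == k
      cands[[next_id]] <- structure(list(
        id = next_id, slice_index = s,
        bbox = c(r0 = r0, c0 = c0, r1 = r1, c1 = c1),
        patch = sl[r0:r1, c0:c1],
        brain_patch = br[r0:r1, c0:c1],
        mask = comp,
        area_px = sum(labels == k)), class = "lesion_candidate")
      union[, , s][labels == k] <- TRUE
      next_id <- next_id + 1L
    }
  }
  structure(list(candidates = cands, mask = binary_mask(union),
                 thresholds = do.call(rbind, thr_rows)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidates on %d slices, %d voxels\n",
              length(x$candidates), nrow(x$thresholds), sum(x$mask$voxels)))
  invisible(x)
}

# 8-connected component labeling of a logical matrix by BFS over the
# (sparse) foreground; returns an integer matrix, 0 = background
label_components_8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  labels <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (!length(idx)) return(labels)
  lab <- 0L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      nb_r <- r + dr; nb_c <- cl + dc
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[fg[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- lab
        queue <- c(queue, nb)
      }
    }
  }
  labels
}
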