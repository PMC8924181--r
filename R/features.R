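#' Intensity-histogram features of a patch
#'
#' First- to fourth-order statistics of the discrete gray-level
#' distribution of the masked patch voxels on the standardized scale:
#' mean, variance, skewness and kurtosis (moment-standardized,
#' `m3 / sigma^3` and `m4 / sigma^4`, so a Gaussian has kurtosis 3),
#' energy (`sum p^2`) and Shannon entropy in bits (`-sum p log2 p`, with
#' `0 log 0 := 0`). A constant patch takes the degenerate convention
#' skewness = kurtosis = 0, energy = 1, entropy = 0.
#'
#' @param patch numeric matrix of standardized intensities.
#' @param mask logical matrix; features use masked voxels only.
#' @return Named list: `mean`, `variance`, `skewness`, `kurtosis`,
#'   `energy`, `entropy`.
#' @export
histogram_features <- function(patch, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(patch))
  stopifnot(identical(dim(patch), dim(mask)))
  x <- as.numeric(patch[mask])
  if (!length(x)) stop("histogram_features: empty mask")
  tab <- table(x)
  p <- as.numeric(tab) / length(x)
  g <- as.numeric(names(tab))
  mu <- sum(g * p)
  v <- sum((g - mu)^2 * p)
  if (v > 0) {
    skew <- sum((g - mu)^3 * p) / v^1.5
    kurt <- sum((g - mu)^4 * p) / v^2
  } else {
    skew <- 0; kurt <- 0
  }
  list(mean = mu, variance = v, skewness = skew, kurtosis = kurt,
       energy = sum(p^2), entropy = -sum(p * log2(p)))
}

#' Quantize a patch by 1-D k-means on its masked intensities
#'
#' The embedded-clustering step: patch intensities are clustered with
#' Lloyd's k-means (deterministic initialization at the `L` equally spaced
#' quantiles of the masked intensities, probabilities `(i - 0.5) / L`),
#' centers are relabeled in ascending intensity order so label order is
#' intensity order, and every masked voxel takes the label of its nearest
#' center (ties to the lower label). Unmasked voxels carry `NA`, a
#' sentinel excluded from GLCM pairs. Clustering is exact on the weighted
#' unique-intensity histogram, so runtime does not grow with patch size.
#'
#' @param patch numeric matrix.
#' @param mask logical matrix (default: all).
#' @param n_clusters requested number of gray levels L; reduced with a
#'   warning if the patch has fewer distinct intensities.
#' @param max_iter Lloyd iteration cap.
#' @param seed unused by the deterministic initializer; accepted for
#'   interface stability.
#' @return Object of class `quantized_patch`: `labels` (integer matrix,
#'   0-based labels, `NA` outside mask), `centers` (ascending),
#'   `n_clusters` (actual), `method`.
#' @export
kmeans_quantize <- function(patch, mask = NULL, n_clusters = 5L,
                            max_iter = 100L, seed = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(patch))
  stopifnot(identical(dim(patch), dim(mask)), n_clusters >= 1)
  x <- as.numeric(patch[mask])
  if (length(x) < n_clusters)
    stop("kmeans_quantize: fewer masked voxels than clusters")
  tab <- table(x)
  ux <- as.numeric(names(tab))
  w <- as.numeric(tab)
  L <- as.integer(n_clusters)
  if (length(ux) < L) {
    warning("kmeans_quantize: only ", length(ux),
            " distinct intensities; reducing n_clusters")
    L <- length(ux)
  }
  if (L == 1L) {
    centers <- sum(w * ux) / sum(w)
    labels_u <- rep(0L, length(ux))
  } else {
    centers <- unname(stats::quantile(x, (seq_len(L) - 0.5) / L, type = 7))
    centers <- sort(unique(centers))
    while (length(centers) < L) {  # quantile ties on skewed data
      gap <- which.max(diff(centers))
      centers <- sort(c(centers, mean(centers[gap + 0:1])))
    }
    for (it in seq_len(max_iter)) {
      assign <- nearest_center(ux, centers)
      new_centers <- vapply(seq_len(L), function(k) {
        sel <- assign == k
        if (any(sel)) sum(w[sel] * ux[sel]) / sum(w[sel]) else centers[k]
      }, numeric(1))
      if (max(abs(new_centers - centers)) < 1e-10) { centers <- new_centers; break }
      centers <- new_centers
    }
    ord <- order(centers)
    centers <- centers[ord]
    labels_u <- match(nearest_center(ux, centers), seq_len(L)) - 1L
  }
  lut <- stats::setNames(labels_u, as.character(ux))
  labels <- matrix(NA_integer_, nrow(patch), ncol(patch))
  labels[mask] <- lut[as.character(x)]
  structure(list(labels = labels, centers = centers, n_clusters = L,
                 method = "kmeans"), class = "quantized_patch")
}

# index of nearest center; exact ties go to the lower label
nearest_center <- function(x, centers) {
  d <- abs(outer(x, centers, "-"))
  max.col(-d, ties.method = "first")
}

#' Quantize a patch by equal-count quantile bins
#'
#' The linear-scaling baseline the embedded clustering is compared
#' against: bin edges at equally spaced quantiles of the masked
#' intensities, label = bin index.
#'
#' @inheritParams kmeans_quantize
#' @return Object of class `quantized_patch` (`method = "quantile"`);
#'   centers are the bin-wise mean intensities.
#' @export
quantile_quantize <- function(patch, mask = NULL, n_clusters = 5L) {
  if (is.null(mask)) mask <- array(TRUE, dim(patch))
  stopifnot(identical(dim(patch), dim(mask)), n_clusters >= 1)
  x <- as.numeric(patch[mask])
  if (length(x) < n_clusters)
    stop("quantile_quantize: fewer masked voxels than clusters")
  L <- as.integer(n_clusters)
  n_distinct <- length(unique(x))
  if (n_distinct < L) {
    warning("quantile_quantize: only ", n_distinct,
            " distinct intensities; reducing n_clusters")
    L <- n_distinct
  }
  if (L == 1L) {
    lab_x <- rep(0L, length(x))
  } else {
    edges <- unique(stats::quantile(x, seq_len(L - 1) / L, type = 7))
    lab_x <- findInterval(x, edges, left.open = TRUE)
  }
  centers <- vapply(sort(unique(lab_x)), function(k) mean(x[lab_x == k]),
                    numeric(1))
  # compact labels in case of empty bins from tied edges
  lab_x <- match(lab_x, sort(unique(lab_x))) - 1L
  labels <- matrix(NA_integer_, nrow(patch), ncol(patch))
  labels[mask] <- lab_x
  structure(list(labels = labels, centers = centers,
                 n_clusters = length(centers), method = "quantile"),
            class = "quantized_patch")
}

#' Reconstruct a patch from its quantization
#'
#' `centers[labels]`; used to measure quantization error.
#' @param q a `quantized_patch`.
#' @return Numeric matrix with `NA` outside the mask.
#' @export
reconstruct_patch <- function(q) {
  out <- matrix(NA_real_, nrow(q$labels), ncol(q$labels))
  ok <- !is.na(q$labels)
  out[ok] <- q$centers[q$labels[ok] + 1L]
  out
}

#' Gray-level co-occurrence matrix of a quantized patch
#'
#' Counts ordered pixel pairs (current level n, displaced level m) at the
#' given orientation and unit distance. The orientation-to-offset map in
#' (row, col) is 0 deg -> (0, 1), 45 -> (-1, 1), 90 -> (-1, 0),
#' 135 -> (-1, -1) (Haralick convention). Pairs are counted one-directed
#' (no symmetrization); relative to writing the displacement with a
#' negative sign this transposes the count matrix, which leaves contrast,
#' energy and homogeneity unchanged. Pairs touching a sentinel (`NA`)
#' pixel are skipped and the normalizer is reduced accordingly, so the
#' probabilities always sum to one.
#'
#' @param q a `quantized_patch`.
#' @param orientation_deg one of 0, 45, 90, 135.
#' @param offset optional explicit (row, col) displacement overriding
#'   `orientation_deg`.
#' @return Object of class `glcm`: `counts`, `probabilities`, `offset`,
#'   `orientation_deg`, `n_pairs`.
#' @export
compute_glcm <- function(q, orientation_deg = 0, offset = NULL) {
  stopifnot(inherits(q, "quantized_patch"))
  if (is.null(offset)) {
    offset <- switch(as.character(orientation_deg),
                     "0" = c(0L, 1L), "45" = c(-1L, 1L),
                     "90" = c(-1L, 0L), "135" = c(-1L, -1L),
                     stop("compute_glcm: orientation must be 0/45/90/135"))
  }
  lab <- q$labels
  nr <- nrow(lab); nc <- ncol(lab)
  dr <- offset[1]; dc <- offset[2]
  r_cur <- max(1L, 1L - dr):min(nr, nr - dr)
  c_cur <- max(1L, 1L - dc):min(nc, nc - dc)
  if (!length(r_cur) || !length(c_cur) || (nr - abs(dr)) < 1 || (nc - abs(dc)) < 1)
    stop("compute_glcm: patch smaller than offset")
  a <- lab[r_cur, c_cur, drop = FALSE]
  b <- lab[r_cur + dr, c_cur + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  n_pairs <- sum(ok)
  if (n_pairs == 0) stop("compute_glcm: no valid pixel pairs under the mask")
  L <- q$n_clusters
  counts <- matrix(0, L, L)
  tab <- table(factor(a[ok], levels = 0:(L - 1)),
               factor(b[ok], levels = 0:(L - 1)))
  counts[] <- as.numeric(tab)
  structure(list(counts = counts, probabilities = counts / n_pairs,
                 offset = offset, orientation_deg = orientation_deg,
                 n_pairs = n_pairs, dims = dim(lab)),
            class = "glcm")
}

#' Haralick texture features of a GLCM
#'
#' Contrast `sum (i-j)^2 P`, energy `sum P^2`, homogeneity
#' `sum P / (1 + |i-j|)`, and correlation
#' `(sum i j P - mu_x mu_y) / (sigma_x sigma_y)` with marginal means and
#' standard deviations of `P_x`, `P_y`. If `sigma_x * sigma_y = 0`
#' correlation is defined as 0.
#'
#' @param g a `glcm`.
#' @return Named list: `contrast`, `energy`, `correlation`, `homogeneity`.
#' @export
glcm_features <- function(g) {
  P <- g$probabilities
  L <- nrow(P)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  lev <- 0:(L - 1)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px))
  sy <- sqrt(sum((lev - muy)^2 * py))
  corr <- if (sx * sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  list(contrast = sum((i - j)^2 * P),
       energy = sum(P^2),
       correlation = corr,
       homogeneity = sum(P / (1 + abs(i - j))))
}

#' Full 10-scalar feature vector of a lesion candidate
#'
#' Histogram features are computed on the standardized patch within the
#' candidate's component mask; GLCM features on the k-means-quantized
#' (default) patch. By default the GLCM uses the whole margin-dilated
#' patch rectangle masked to brain -- the texture context around the
#' lesion is what discriminates false-positive mimics -- with
#' `glcm_scope = "mask"` restricting it to the component itself. Defaults
#' `n_clusters = 5`, orientation 0 deg, distance (1, 0) are the pipeline's
#' operating point.
#'
#' @param candidate a `lesion_candidate` from [detect_candidates()].
#' @param n_clusters gray levels for quantization.
#' @param orientation_deg GLCM orientation.
#' @param quantizer `"kmeans"` or `"quantile"`.
#' @param glcm_scope `"patch"` or `"mask"`.
#' @return Named numeric vector of 10 features prefixed `h_` (histogram)
#'   and `g_` (GLCM), with attribute `candidate_id`.
#' @export
extract_features <- function(candidate, n_clusters = 5L,
                             orientation_deg = 0,
                             quantizer = c("kmeans", "quantile"),
                             glcm_scope = c("patch", "mask")) {
  stopifnot(inherits(candidate, "lesion_candidate"))
  quantizer <- match.arg(quantizer)
  glcm_scope <- match.arg(glcm_scope)
  hf <- histogram_features(candidate$patch, candidate$mask)
  qmask <- if (glcm_scope == "patch") {
    candidate$brain_patch %||% array(TRUE, dim(candidate$patch))
  } else candidate$mask
  q <- suppressWarnings(
    if (quantizer == "kmeans") {
      kmeans_quantize(candidate$patch, qmask, n_clusters)
    } else {
      quantile_quantize(candidate$patch, qmask, n_clusters)
    })
  gf <- glcm_features(compute_glcm(q, orientation_deg))
  out <- c(h_mean = hf$mean, h_variance = hf$variance,
           h_skewness = hf$skewness, h_kurtosis = hf$kurtosis,
           h_energy = hf$energy, h_entropy = hf$entropy,
           g_contrast = gf$contrast, g_energy = gf$energy,
           g_correlation = gf$correlation, g_homogeneity = gf$homogeneity)
  if (any(!is.finite(out))) stop("extract_features: non-finite feature")
  attr(out, "candidate_id") <- candidate$id
  out
}

#' Feature table for a set of candidates
#'
#' @param candidate_set a `candidate_set` (or plain list of candidates).
#' @param ... passed to [extract_features()].
#' @return data.frame: `id`, `slice`, `area_px`, the 10 feature columns.
#' @export
candidate_feature_table <- function(candidate_set, ...) {
  cands <- if (inherits(candidate_set, "candidate_set"))
    candidate_set$candidates else candidate_set
  if (!length(cands))
    return(data.frame(id = integer(), slice = integer(), area_px = integer()))
  rows <- lapply(cands, function(cd) {
    f <- extract_features(cd, ...)
    cbind(data.frame(id = cd$id, slice = cd$slice_index,
                     area_px = cd$area_px), as.data.frame(t(f)))
  })
  do.call(rbind, rows)
}
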