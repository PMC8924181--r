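#' Local Outlier Factor on scalar intensities
#'
#' The boundary-refinement stage scores voxel intensities against a
#' reference set of known-lesion intensities with the Local Outlier
#' Factor: the ratio of the mean local reachability density of a point's
#' k-nearest reference neighbours to its own. Scores near 1 mark points
#' inside the reference density (lesion-like); scores well above 1 mark
#' outliers (background). The metric is the absolute intensity
#' difference. When a query value coincides with a reference element,
#' exactly one coincident element is excluded from its neighbourhood
#' (the point never counts as its own neighbour).
#'
#' `k_distance`, `reach_dist`, `local_reachability_density` and
#' `lof_score` expose the individual steps; [fit_lof_model()] /
#' [lof_scores()] are the fitted, cached interface the pipeline uses.
#'
#' @param o query intensity (scalar for the step functions).
#' @param ref numeric vector of reference intensities.
#' @param k,min_pts neighbourhood size.
#' @return `k_distance`: distance to the k-th nearest reference point
#'   (ties may enlarge the neighbourhood beyond k).
#' @name lof
NULL

LRD_CAP <- 1e12

#' @rdname lof
#' @export
k_distance <- function(o, ref, k) {
  stopifnot(length(o) == 1, k >= 1)
  d <- sort_excluding_self(o, ref)
  if (k > length(d)) stop("k_distance: k exceeds reference size")
  sort(d)[k]
}

sort_excluding_self <- function(o, ref) {
  d <- abs(ref - o)
  hit <- which(d == 0)
  if (length(hit)) d <- d[-hit[1]]
  d
}

#' @rdname lof
#' @param p second query intensity for `reach_dist`.
#' @export
reach_dist <- function(p, o, ref, k) {
  max(k_distance(o, ref, k), abs(p - o))
}

#' @rdname lof
#' @export
local_reachability_density <- function(o, ref, min_pts) {
  m <- fit_lof_model(ref, min_pts = min_pts, max_reference = Inf)
  query_lrd(m, o)
}

#' @rdname lof
#' @export
lof_score <- function(o, ref, min_pts) {
  m <- fit_lof_model(ref, min_pts = min_pts, max_reference = Inf)
  lof_scores(m, o)
}

#' Fit a lesion-intensity LOF reference model
#'
#' Stores the (optionally downsampled) sorted reference intensities and
#' precomputes each reference point's k-distance and local reachability
#' density, so scoring queries is cheap. Degenerate duplicate-heavy
#' neighbourhoods (all reachability distances zero) take a capped density
#' (`1e12`), a documented sentinel.
#'
#' @param reference numeric vector of training lesion intensities.
#' @param min_pts neighbourhood size (default 20).
#' @param threshold LOF value tau at or below which a voxel counts as
#'   lesion-like (default 1.5).
#' @param max_reference reference kept after seeded stratified
#'   downsampling (default 10000; `Inf` for exact mode).
#' @param seed downsampling seed.
#' @return Object of class `lof_model`.
#' @export
fit_lof_model <- function(reference, min_pts = 20L, threshold = 1.5,
                          max_reference = 10000L, seed = 1L) {
  reference <- as.numeric(reference)
  stopifnot(length(reference) >= 2, min_pts >= 1,
            min_pts <= length(reference) - 1, threshold >= 1)
  if (is.finite(max_reference) && length(reference) > max_reference) {
    reference <- stratified_downsample(reference, max_reference, seed)
  }
  sr <- sort(reference)
  n <- length(sr)
  kd <- numeric(n)
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    res <- neighborhood_sorted(sr, sr[i], min_pts, self_index = i)
    kd[i] <- res$kdist
    nbr[[i]] <- res$idx
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    rd <- pmax(kd[nbr[[i]]], abs(sr[nbr[[i]]] - sr[i]))
    m <- mean(rd)
    lrd[i] <- if (m > 0) 1 / m else LRD_CAP
  }
  structure(list(reference = sr, kdist = kd, lrd = lrd,
                 min_pts = as.integer(min_pts), threshold = threshold),
            class = "lof_model")
}

#' @export
print.lof_model <- function(x, ...) {
  cat(sprintf("lof_model: %d reference intensities in [%g, %g], MinPts %d, tau %g\n",
              length(x$reference), min(x$reference), max(x$reference),
              x$min_pts, x$threshold))
  invisible(x)
}

# k nearest neighbours of x in sorted vector sr, excluding one coincident
# element (or the element self_index when given); ties at the k-distance
# enlarge the neighbourhood
neighborhood_sorted <- function(sr, x, k, self_index = NA) {
  n <- length(sr)
  pos <- findInterval(x, sr)
  win <- max(1L, pos - k - 1L):min(n, pos + k + 2L)
  d <- abs(sr[win] - x)
  if (!is.na(self_index) && self_index %in% win) {
    d[match(self_index, win)] <- Inf
  } else {
    hit <- which(d == 0)
    if (length(hit)) d[hit[1]] <- Inf
  }
  kdist <- sort(d)[k]
  # all reference points within kdist; the interval endpoints are located
  # by search, then membership is decided by the same |sr - x| arithmetic
  # used for kdist so boundary ties are exact
  a <- max(1L, findInterval(x - kdist, sr, left.open = TRUE) - 1L)
  b <- min(n, findInterval(x + kdist, sr) + 2L)
  idx <- (a:b)[abs(sr[a:b] - x) <= kdist]
  if (!is.na(self_index)) {
    idx <- idx[idx != self_index]
  } else {
    hit <- which(sr[idx] == x)
    if (length(hit)) idx <- idx[-hit[1]]
  }
  list(kdist = kdist, idx = idx)
}

query_lrd <- function(model, x) {
  vapply(as.numeric(x), function(xi) {
    res <- neighborhood_sorted(model$reference, xi, model$min_pts)
    rd <- pmax(model$kdist[res$idx], abs(model$reference[res$idx] - xi))
    m <- mean(rd)
    if (m > 0) 1 / m else LRD_CAP
  }, numeric(1))
}

#' Score intensities against a fitted LOF model
#'
#' @param model a `lof_model`.
#' @param x numeric vector of query intensities.
#' @return LOF score per query (about 1 inside the reference density).
#' @export
lof_scores <- function(model, x) {
  x <- as.numeric(x)
  ux <- unique(x)
  scores <- vapply(ux, function(xi) {
    res <- neighborhood_sorted(model$reference, xi, model$min_pts)
    rd <- pmax(model$kdist[res$idx], abs(model$reference[res$idx] - xi))
    m <- mean(rd)
    lrd_o <- if (m > 0) 1 / m else LRD_CAP
    mean(model$lrd[res$idx]) / lrd_o
  }, numeric(1))
  scores[match(x, ux)]
}

#' Refine a candidate's boundary with the LOF model
#'
#' Every voxel of the candidate patch (within brain) is scored; voxels
#' with LOF at most the model's threshold -- inliers with respect to the
#' lesion intensity model -- form the refined mask. An empty refinement
#' means the candidate is dropped by the caller.
#'
#' @param candidate a `lesion_candidate`.
#' @param model a `lof_model`.
#' @param tau optional threshold override.
#' @return List of class `voxel_lof_scores`: `scores` (matrix, `NA`
#'   outside brain), `refined_mask` (logical matrix over the patch).
#' @export
refine_boundary <- function(candidate, model, tau = NULL) {
  stopifnot(inherits(candidate, "lesion_candidate"),
            inherits(model, "lof_model"))
  tau <- tau %||% model$threshold
  brain <- candidate$brain_patch %||% array(TRUE, dim(candidate$patch))
  scores <- matrix(NA_real_, nrow(candidate$patch), ncol(candidate$patch))
  scores[brain] <- lof_scores(model, candidate$patch[brain])
  refined <- !is.na(scores) & scores <= tau
  structure(list(scores = scores, refined_mask = refined),
            class = "voxel_lof_scores")
}

# seeded stratified downsample: proportional sampling within quantile strata
stratified_downsample <- function(x, size, seed, n_strata = 100L) {
  set.seed(seed)
  sx <- sort(x)
  strata <- cut(seq_along(sx), breaks = n_strata, labels = FALSE)
  keep <- unlist(lapply(split(seq_along(sx), strata), function(idx) {
    take <- max(1L, round(length(idx) * size / length(sx)))
    if (take >= length(idx)) idx else sort(sample(idx, take))
  }), use.names = FALSE)
  sx[keep]
}
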