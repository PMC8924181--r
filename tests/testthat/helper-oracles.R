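# Independent oracles used across the suite. These deliberately follow the
# defining formulas step by step (quadratic-time loops, explicit sums) and
# share no code with the package implementations they check.

# --- Local Outlier Factor, literal O(n^2) chain --------------------------

# k-distance of value x against reference set, excluding one coincident
# element (a point is never its own neighbour)
oracle_kdist <- function(x, ref, k) {
  d <- abs(ref - x)
  hit <- which(d == 0)
  if (length(hit)) d <- d[-hit[1]]
  sort(d)[k]
}

oracle_lof <- function(queries, ref, k) {
  n <- length(ref)
  kd <- numeric(n)
  lrd_ref <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- abs(ref - ref[i])
    d[i] <- Inf
    kd[i] <- sort(d)[k]
    nbrs[[i]] <- which(d <= kd[i])
  }
  for (i in seq_len(n)) {
    rd <- vapply(nbrs[[i]], function(j) max(kd[j], abs(ref[j] - ref[i])),
                 numeric(1))
    m <- mean(rd)
    lrd_ref[i] <- if (m > 0) 1 / m else 1e12
  }
  vapply(queries, function(x) {
    d <- abs(ref - x)
    hit <- which(d == 0)
    excl <- if (length(hit)) hit[1] else 0L
    dd <- d
    if (excl > 0) dd[excl] <- Inf
    kdx <- sort(dd)[k]
    nb <- which(dd <= kdx)
    rd <- vapply(nb, function(j) max(kd[j], d[j]), numeric(1))
    m <- mean(rd)
    lrd_o <- if (m > 0) 1 / m else 1e12
    mean(lrd_ref[nb]) / lrd_o
  }, numeric(1))
}

# --- ICC(2,1) from aov() mean squares ------------------------------------

oracle_icc21 <- function(a, b) {
  n <- length(a)
  dat <- data.frame(y = c(a, b),
                    subject = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = dat))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  k <- 2
  (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
}

# --- small deterministic phantom for fast tests --------------------------

tiny_phantom <- function(seed = 11, n_lesions = 3, n_mimics = 3,
                         n_slices = 4L, dims = c(128L, 128L),
                         contrast = 4500, radius = 5, ...) {
  lesions <- if (n_lesions > 0) {
    set.seed(seed * 13L)
    data.frame(slice = rep_len(seq_len(n_slices), n_lesions),
               row = round(stats::runif(n_lesions, dims[1] * 0.35, dims[1] * 0.6)),
               col = round(stats::runif(n_lesions, dims[2] * 0.3, dims[2] * 0.42)),
               radius_px = radius, contrast = contrast,
               texture_sigma = 0.12 * contrast)
  } else NULL
  mimics <- if (n_mimics > 0) {
    set.seed(seed * 17L)
    data.frame(kind = rep_len(c("streak", "rim_fragment", "punctate_noise"),
                              n_mimics),
               slice = rep_len(seq_len(n_slices), n_mimics),
               row = round(stats::runif(n_mimics, dims[1] * 0.4, dims[1] * 0.6)),
               col = round(stats::runif(n_mimics, dims[2] * 0.55, dims[2] * 0.68)))
  } else NULL
  generate_phantom(phantom_spec(n_slices = n_slices, slice_dims = dims,
                                lesions = lesions, fp_mimics = mimics,
                                seed = seed, ...))
}

# standardized volume + candidates for one tiny phantom
tiny_detection <- function(seed = 11, ...) {
  b <- tiny_phantom(seed, ...)
  sv <- standardize(b$flair, fit_landmark_map(b$flair, b$brain))
  cs <- detect_candidates(sv, b$brain)
  list(bundle = b, sv = sv, cs = cs)
}
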