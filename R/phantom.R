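#' Specify a synthetic FLAIR phantom
#'
#' Describes a skull-stripped multi-slice FLAIR-like phantom: an
#' elliptical brain per slice with a WM core, a thin GM ribbon and CSF
#' ventricles (intensity order CSF < GM < WM), a smooth multiplicative
#' bias field, additive noise (Gaussian or Rician), hyperintense lesions
#' with a Gaussian radial profile and correlated internal texture, and
#' hyperintense false-positive mimics whose texture and histogram shape
#' differ from lesions (alternating-intensity streaks, bimodal rim
#' fragments, punctate noise clusters).
#'
#' Lesions are given as a data.frame with columns `slice`, `row`, `col`,
#' `radius_px`, `contrast`, `texture_sigma`; the half-peak contour of the
#' Gaussian profile sits exactly at `radius_px`, and ground truth is the
#' set of voxels whose lesion contribution exceeds half the peak
#' contrast. Mimics are a data.frame with columns `kind` (`streak`,
#' `rim_fragment`, `punctate_noise`), `slice` and `row`/`col` seeds.
#'
#' @param n_slices number of axial slices.
#' @param slice_dims c(rows, cols).
#' @param tissue_means c(CSF, GM, WM) on the 16-bit native scale,
#'   strictly increasing.
#' @param noise_sigma additive noise standard deviation.
#' @param bias_amplitude multiplicative bias amplitude in `[0, 1)`.
#' @param lesions,fp_mimics data.frames as above (possibly empty).
#' @param rician use Rician instead of Gaussian noise.
#' @param geometry a [volume_geometry()].
#' @param seed the single seed all randomness flows from.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 10L, slice_dims = c(256L, 256L),
                         tissue_means = c(csf = 2500, gm = 8500, wm = 12000),
                         noise_sigma = 200, bias_amplitude = 0.03,
                         lesions = NULL, fp_mimics = NULL,
                         rician = FALSE,
                         geometry = volume_geometry(), seed = 1L) {
  stopifnot(n_slices >= 1, length(slice_dims) == 2,
            length(tissue_means) == 3, all(diff(tissue_means) > 0),
            noise_sigma >= 0, bias_amplitude >= 0, bias_amplitude < 1)
  lesions <- lesions %||% empty_lesion_df()
  fp_mimics <- fp_mimics %||% empty_mimic_df()
  stopifnot(all(lesions$contrast > 0),
            all(lesions$slice >= 1), all(lesions$slice <= n_slices))
  structure(list(n_slices = as.integer(n_slices),
                 slice_dims = as.integer(slice_dims),
                 tissue_means = tissue_means,
                 noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 lesions = lesions, fp_mimics = fp_mimics,
                 rician = rician, geometry = geometry,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

empty_lesion_df <- function() {
  data.frame(slice = integer(), row = numeric(), col = numeric(),
             radius_px = numeric(), contrast = numeric(),
             texture_sigma = numeric())
}
empty_mimic_df <- function() {
  data.frame(kind = character(), slice = integer(), row = numeric(),
             col = numeric())
}

# slice-wise brain geometry shared by the generator and lesion placement
phantom_layout <- function(spec, s) {
  d <- spec$slice_dims
  scale <- 0.86 + 0.14 * sin(pi * (s - 0.5) / spec$n_slices)
  list(cr = (d[1] + 1) / 2, cc = (d[2] + 1) / 2,
       a = 0.42 * d[1] * scale, b = 0.36 * d[2] * scale,
       wm_scale = 0.88,
       vent = list(dr = 0.04 * d[1], dc = 0.085 * d[2],
                   va = 0.10 * d[1] * scale, vb = 0.035 * d[2] * scale))
}

#' Generate a phantom from its spec
#'
#' Deterministic given the spec (all randomness flows from `spec$seed`):
#' regenerating from the same spec is bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `phantom_bundle`: `flair` ([gray_volume()]),
#'   `brain`, `gt_lesions` ([binary_mask()]), `gt_tissue` (integer array,
#'   0 = background, 1 = CSF, 2 = GM, 3 = WM), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- c(spec$slice_dims, spec$n_slices)
  flair <- array(0, d)
  brain <- array(FALSE, d)
  tissue <- array(0L, d)
  gt <- array(FALSE, d)
  phases <- stats::runif(3, 0, 2 * pi)

  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)

  for (s in seq_len(d[3])) {
    ly <- phantom_layout(spec, s)
    e_brain <- ((rows - ly$cr) / ly$a)^2 + ((cols - ly$cc) / ly$b)^2
    in_brain <- e_brain <= 1
    in_wm <- e_brain <= ly$wm_scale^2
    in_vent <- (((rows - ly$cr - ly$vent$dr) / ly$vent$va)^2 +
                  ((cols - ly$cc - ly$vent$dc) / ly$vent$vb)^2 <= 1) |
               (((rows - ly$cr - ly$vent$dr) / ly$vent$va)^2 +
                  ((cols - ly$cc + ly$vent$dc) / ly$vent$vb)^2 <= 1)
    lab <- matrix(0L, d[1], d[2])
    lab[in_brain] <- 2L                 # GM ribbon
    lab[in_wm] <- 3L                    # WM core
    lab[in_vent & in_brain] <- 1L       # CSF ventricles
    base <- matrix(0, d[1], d[2])
    base[lab > 0L] <- spec$tissue_means[lab[lab > 0L]]

    # lesions of this slice
    lesion_add <- matrix(0, d[1], d[2])
    gt_slice <- matrix(FALSE, d[1], d[2])
    les <- spec$lesions[spec$lesions$slice == s, , drop = FALSE]
    if (nrow(les)) {
      for (i in seq_len(nrow(les))) {
        sgm <- les$radius_px[i] / sqrt(2 * log(2))
        r2 <- (rows - les$row[i])^2 + (cols - les$col[i])^2
        prof <- les$contrast[i] * exp(-r2 / (2 * sgm^2))
        prof[prof < 0.02 * les$contrast[i]] <- 0
        if (les$texture_sigma[i] > 0) {
          tex <- correlated_noise(d[1], d[2], les$texture_sigma[i])
          lesion_add <- lesion_add + prof * (1 + tex / les$contrast[i])
        } else {
          lesion_add <- lesion_add + prof
        }
        gt_slice <- gt_slice | (prof > les$contrast[i] / 2)
      }
      gt_slice <- gt_slice & in_brain
    }

    # false-positive mimics (lesions take priority on collision)
    mimic_add <- matrix(0, d[1], d[2])
    mim <- spec$fp_mimics[spec$fp_mimics$slice == s, , drop = FALSE]
    if (nrow(mim)) {
      for (i in seq_len(nrow(mim))) {
        mimic_add <- mimic_add +
          render_mimic(mim$kind[i], mim$row[i], mim$col[i], d[1], d[2])
      }
      collide <- mimic_add > 0 & gt_slice
      if (any(collide)) {
        mimic_add[collide] <- 0
        message("generate_phantom: ", sum(collide),
                " mimic voxel(s) overlapped a lesion; lesion kept")
      }
      mimic_add[!in_brain] <- 0
    }

    bias <- 1 + spec$bias_amplitude *
      bias_field(rows / d[1], cols / d[2], s / d[3], phases)
    img <- (base + lesion_add + mimic_add) * bias
    noise <- matrix(stats::rnorm(d[1] * d[2], 0, spec$noise_sigma), d[1], d[2])
    img <- if (spec$rician) {
      n2 <- matrix(stats::rnorm(d[1] * d[2], 0, spec$noise_sigma), d[1], d[2])
      sqrt((img + noise)^2 + n2^2)
    } else img + noise
    img[!in_brain] <- 0
    flair[, , s] <- pmin(pmax(round(img), 0), 65535)
    brain[, , s] <- in_brain
    tissue[, , s] <- lab
    gt[, , s] <- gt_slice
  }
  structure(list(flair = gray_volume(flair, spec$geometry),
                 brain = binary_mask(brain),
                 gt_lesions = binary_mask(gt),
                 gt_tissue = tissue, spec = spec),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("phantom_bundle: %s slices, GT load %.3f mL (%d lesions, %d mimics)\n",
              paste(dim(x$flair$voxels), collapse = "x"),
              mask_volume_ml(x$gt_lesions, x$flair$geometry),
              nrow(x$spec$lesions), nrow(x$spec$fp_mimics)))
  invisible(x)
}

# smooth low-frequency multiplicative field in [-1, 1]
bias_field <- function(u, v, w, phases) {
  f <- sin(2 * pi * (0.55 * u) + phases[1]) *
    cos(2 * pi * (0.45 * v) + phases[2]) +
    0.5 * sin(2 * pi * (0.35 * (u + v)) + phases[3] + w)
  f / 1.5
}

# spatially correlated noise: white noise box-blurred twice, rescaled
correlated_noise <- function(nr, nc, sigma) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  m <- box_blur3(box_blur3(m))
  m * (sigma / stats::sd(m))
}

box_blur3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, 1:(nr - 1)), ]; dn <- m[c(2:nr, nr), ]
  v <- (up + m + dn) / 3
  lf <- v[, c(1, 1:(nc - 1))]; rt <- v[, c(2:nc, nc)]
  (lf + v + rt) / 3
}

# draw one mimic; returns an additive intensity matrix
render_mimic <- function(kind, row, col, nr, nc) {
  add <- matrix(0, nr, nc)
  if (kind == "streak") {
    theta <- stats::runif(1, 0, pi)
    len <- round(stats::runif(1, 12, 25))
    thick <- sample(1:2, 1)
    base <- stats::runif(1, 4200, 5200)
    amp <- stats::runif(1, 1200, 1800)
    for (i in 0:(len - 1)) {
      r <- round(row + i * cos(theta)); c <- round(col + i * sin(theta))
      val <- base + amp * (-1)^i
      for (t in 0:(thick - 1)) {
        rr <- r + t
        if (rr >= 1 && rr <= nr && c >= 1 && c <= nc) add[rr, c] <- val
      }
    }
  } else if (kind == "rim_fragment") {
    theta0 <- stats::runif(1, 0, 2 * pi)
    dtheta <- stats::runif(1, 0.4, 0.9)
    rad <- stats::runif(1, 9, 14)
    hi <- stats::runif(1, 7000, 8500)
    lo <- stats::runif(1, 6200, 6800)
    for (th in seq(theta0, theta0 + dtheta, length.out = 40)) {
      for (dr in 0:2) {
        r <- round(row + (rad + dr) * cos(th))
        c <- round(col + (rad + dr) * sin(th))
        if (r >= 1 && r <= nr && c >= 1 && c <= nc)
          add[r, c] <- if (dr == 2) hi else lo
      }
    }
  } else if (kind == "punctate_noise") {
    npx <- sample(4:7, 1)
    for (i in seq_len(npx)) {
      r <- round(row + stats::runif(1, -2, 2))
      c <- round(col + stats::runif(1, -2, 2))
      if (r >= 1 && r <= nr && c >= 1 && c <= nc)
        add[r, c] <- stats::runif(1, 5500, 8000)
    }
  } else stop("render_mimic: unknown kind ", kind)
  add
}

#' Sample a cohort of phantoms within a lesion-load stratum
#'
#' Lesion counts and sizes are sampled so the ground-truth load of every
#' subject falls in the requested stratum (verified on the generated mask
#' and resampled deterministically if voxelization pushed it out). The
#' mild profile emphasises punctate lesions (radius 2--6 px).
#'
#' @param n_subjects cohort size.
#' @param load_profile `"mild"`, `"moderate"`, `"severe"` or `"mixed"`.
#' @param seed cohort seed; subject i derives seed `seed + 1000 * i`.
#' @param ... overrides passed to [phantom_spec()].
#' @return List of `phantom_bundle`.
#' @export
generate_cohort <- function(n_subjects, load_profile = "mild", seed = 1L,
                            ...) {
  stopifnot(n_subjects >= 1)
  profiles <- c("mild", "moderate", "severe")
  lapply(seq_len(n_subjects), function(i) {
    prof <- if (load_profile == "mixed") {
      set.seed(seed + 7L * i)
      sample(profiles, 1, prob = c(0.7, 0.22, 0.08))
    } else load_profile
    for (attempt in 0:24) {
      sseed <- seed + 1000L * i + 37L * attempt
      spec <- sample_phantom_spec(prof, sseed, ...)
      bundle <- generate_phantom(spec)
      load <- mask_volume_ml(bundle$gt_lesions, bundle$flair$geometry)
      ok <- switch(prof, mild = load < 5 && load > 0.3,
                   moderate = load >= 5 && load <= 15,
                   severe = load > 15)
      if (ok) return(bundle)
    }
    stop("generate_cohort: could not hit stratum '", prof, "' for subject ", i)
  })
}

# draw a random phantom_spec whose expected load sits in the stratum
sample_phantom_spec <- function(profile, seed, ...) {
  set.seed(seed)
  args <- list(...)
  n_slices <- args$n_slices %||% 10L
  dims <- args$slice_dims %||% c(256L, 256L)
  geometry <- args$geometry %||% volume_geometry()
  vx_ml <- voxel_volume_mm3(geometry) / 1000
  target_ml <- switch(profile,
                      mild = stats::runif(1, 1.0, 4.2),
                      moderate = stats::runif(1, 5.8, 13.5),
                      severe = stats::runif(1, 16.5, 30))
  radii_pool <- switch(profile,
                       mild = c(2, 3, 4, 5, 6),
                       moderate = c(4, 5, 6, 8, 10),
                       severe = c(8, 10, 12, 14, 16))
  radii_w <- switch(profile,
                    mild = c(0.28, 0.28, 0.22, 0.14, 0.08),
                    moderate = c(0.2, 0.25, 0.25, 0.2, 0.1),
                    severe = c(0.25, 0.25, 0.2, 0.2, 0.1))
  lesions <- empty_lesion_df()
  expected <- 0
  while (expected < target_ml && nrow(lesions) < 120) {
    r <- sample(radii_pool, 1, prob = radii_w)
    s <- sample(seq_len(n_slices), 1)
    pos <- sample_wm_position(dims, n_slices, s, r)
    if (is.null(pos)) next
    contrast <- stats::runif(1, 3800, 5600)
    lesions <- rbind(lesions, data.frame(
      slice = s, row = pos[1], col = pos[2], radius_px = r,
      contrast = contrast, texture_sigma = 0.12 * contrast))
    expected <- expected + pi * r^2 * vx_ml
  }
  n_mimics <- sample(18:28, 1)
  kinds <- sample(c("streak", "rim_fragment", "punctate_noise"), n_mimics,
                  replace = TRUE, prob = c(0.4, 0.3, 0.3))
  mim <- do.call(rbind, lapply(seq_len(n_mimics), function(j) {
    s <- sample(seq_len(n_slices), 1)
    pos <- sample_wm_position(dims, n_slices, s, 6)
    if (is.null(pos)) return(NULL)
    data.frame(kind = kinds[j], slice = s, row = pos[1], col = pos[2])
  })) %||% empty_mimic_df()
  do.call(phantom_spec, utils::modifyList(
    list(n_slices = n_slices, slice_dims = dims, geometry = geometry,
         lesions = lesions, fp_mimics = mim, seed = seed),
    args[setdiff(names(args), c("n_slices", "slice_dims", "geometry"))]))
}

# rejection-sample a point inside the WM core, clear of the ventricles
sample_wm_position <- function(dims, n_slices, s, radius) {
  spec0 <- list(slice_dims = dims, n_slices = n_slices)
  ly <- phantom_layout(spec0, s)
  for (i in 1:50) {
    r <- stats::runif(1, 1, dims[1])
    c <- stats::runif(1, 1, dims[2])
    e <- ((r - ly$cr) / (ly$a * ly$wm_scale - radius - 3))^2 +
      ((c - ly$cc) / (ly$b * ly$wm_scale - radius - 3))^2
    v1 <- ((r - ly$cr - ly$vent$dr) / (ly$vent$va + radius + 2))^2 +
      ((c - ly$cc - ly$vent$dc) / (ly$vent$vb + radius + 2))^2
    v2 <- ((r - ly$cr - ly$vent$dr) / (ly$vent$va + radius + 2))^2 +
      ((c - ly$cc + ly$vent$dc) / (ly$vent$vb + radius + 2))^2
    if (e <= 1 && v1 > 1 && v2 > 1) return(c(round(r), round(c)))
  }
  NULL
}

#' Build a labeled training set from a phantom cohort
#'
#' Standardizes every phantom against the cohort scale, runs candidate
#' detection and feature extraction, labels candidates by ground-truth
#' overlap, and optionally subsamples to a requested non-WML : WML
#' imbalance ratio.
#'
#' @param cohort list of `phantom_bundle`.
#' @param imbalance_ratio target `non-WML / WML` count ratio (the
#'   clinical training structure is about 7.4); `NULL` keeps every
#'   candidate.
#' @param seed subsampling seed.
#' @param ... detection parameter overrides for [detect_candidates()].
#' @return A `training_set`; attribute `subject` maps rows to cohort
#'   indices, attribute `standard_landmarks` carries the cohort scale.
#' @export
generate_training_set <- function(cohort, imbalance_ratio = 7.4, seed = 1L,
                                  ...) {
  std <- fit_standard_scale(lapply(cohort, `[[`, "flair"),
                            lapply(cohort, `[[`, "brain"))
  feats <- list(); labels <- list(); subject <- list()
  for (i in seq_along(cohort)) {
    b <- cohort[[i]]
    sv <- standardize(b$flair, fit_landmark_map(b$flair, b$brain,
                                                target_landmarks = std))
    cs <- detect_candidates(sv, b$brain, ...)
    if (!length(cs$candidates)) next
    ft <- candidate_feature_table(cs)
    feats[[length(feats) + 1]] <- ft[wml_feature_names]
    labels[[length(labels) + 1]] <- label_candidates(cs, b$gt_lesions)
    subject[[length(subject) + 1]] <- rep(i, nrow(ft))
  }
  if (!length(feats)) stop("generate_training_set: no candidates detected")
  X <- do.call(rbind, feats)
  y <- factor(unlist(lapply(labels, as.character)),
              levels = c("non-WML", "WML"))
  subj <- unlist(subject)
  if (sum(y == "non-WML") < 2 || sum(y == "WML") < 2)
    stop("generate_training_set: insufficient candidates in one class (",
         sum(y == "WML"), " WML, ", sum(y == "non-WML"), " non-WML); ",
         "cohort needs both lesions and mimics")
  keep <- seq_along(y)
  if (!is.null(imbalance_ratio)) {
    set.seed(seed)
    n_w <- sum(y == "WML"); n_n <- sum(y == "non-WML")
    if (n_n / n_w > imbalance_ratio) {
      drop_from <- which(y == "non-WML")
      n_keep <- round(imbalance_ratio * n_w)
    } else {
      drop_from <- which(y == "WML")
      cand <- pmax(2, c(floor(n_n / imbalance_ratio),
                        ceiling(n_n / imbalance_ratio)))
      n_keep <- cand[which.min(abs(n_n / cand - imbalance_ratio))]
    }
    keep <- sort(c(setdiff(seq_along(y), drop_from),
                   sample(drop_from, n_keep)))
  }
  ts <- training_set(X[keep, , drop = FALSE], y[keep], keep)
  attr(ts, "subject") <- subj[keep]
  attr(ts, "standard_landmarks") <- std
  ts
}
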