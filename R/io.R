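#' Read a grayscale volume from disk
#'
#' Supports NIfTI-1 (`.nii` / `.nii.gz`) files and, as a fixture dialect, a
#' directory of per-slice TIFF images named `slice_###.tiff` with an
#' optional `geometry.yaml` sidecar. In-plane spacing and slice thickness
#' are taken from the NIfTI header (or the sidecar); anything missing falls
#' back to `default_geometry`. The inter-slice gap has no NIfTI header slot
#' and always comes from the sidecar or the default.
#'
#' @param path file or directory path.
#' @param default_geometry geometry used where the source carries none.
#' @param scale_max native dynamic range recorded on the volume.
#' @return A [gray_volume()].
#' @export
load_volume <- function(path, default_geometry = volume_geometry(),
                        scale_max = 65535L) {
  if (!file.exists(path)) stop("load_volume: no such path: ", path)
  if (dir.exists(path)) {
    return(load_tiff_stack(path, default_geometry, scale_max))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)
  arr <- array(as.vector(img), d)  # plain array, niftiImage attributes dropped
  if (anyNA(arr) || any(arr < 0) || any(arr != floor(arr)))
    stop("load_volume: volume has negative or non-integer intensities")
  pd <- RNifti::pixdim(img)
  geom <- default_geometry
  if (length(pd) >= 3 && all(pd[1:3] > 0)) {
    geom <- volume_geometry(pd[1:2], pd[3], default_geometry$inter_slice_gap_mm)
  }
  gray_volume(arr, geom, scale_max = max(scale_max, max(arr)))
}

load_tiff_stack <- function(path, default_geometry, scale_max) {
  files <- sort(list.files(path, pattern = "^slice_\\d+\\.tiff?$",
                           full.names = TRUE))
  if (!length(files)) stop("load_volume: no slice_###.tiff files in ", path)
  slices <- lapply(files, function(f) {
    m <- tiff::readTIFF(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]  # grayscale only
    round(m * scale_max)
  })
  arr <- array(0, c(dim(slices[[1]]), length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]
  geom <- default_geometry
  side <- file.path(path, "geometry.yaml")
  if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    geom <- volume_geometry(
      unlist(y$in_plane_spacing_mm %||% default_geometry$in_plane_spacing_mm),
      y$slice_thickness_mm %||% default_geometry$slice_thickness_mm,
      y$inter_slice_gap_mm %||% default_geometry$inter_slice_gap_mm)
  }
  gray_volume(arr, geom, scale_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a grayscale volume
#'
#' NIfTI-1 for `.nii`/`.nii.gz` paths; a `slice_###.tiff` stack (16-bit)
#' plus `geometry.yaml` when `path` has no recognised extension, in which
#' case it is created as a directory.
#'
#' @param volume a [gray_volume()].
#' @param path destination.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "gray_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    write_nifti_array(volume$voxels, volume$geometry, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    d <- dim(volume$voxels)
    for (i in seq_len(d[3])) {
      tiff::writeTIFF(volume$voxels[, , i] / volume$scale_max,
                      file.path(path, sprintf("slice_%03d.tiff", i)),
                      bits.per.sample = 16L)
    }
    yaml::write_yaml(list(
      in_plane_spacing_mm = volume$geometry$in_plane_spacing_mm,
      slice_thickness_mm = volume$geometry$slice_thickness_mm,
      inter_slice_gap_mm = volume$geometry$inter_slice_gap_mm,
      scale_max = volume$scale_max), file.path(path, "geometry.yaml"))
  }
  invisible(path)
}

write_nifti_array <- function(arr, geometry, path) {
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(geometry$in_plane_spacing_mm,
                           geometry$slice_thickness_mm)
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Read / write binary masks
#'
#' Masks are written as 0/1 volumes; loading enforces that only the values
#' 0 and 1 occur so a mask round-trips bit-exactly.
#'
#' @param mask a [binary_mask()].
#' @param path file (`.nii`/`.nii.gz`) or stack-directory path.
#' @return `load_mask` returns a [binary_mask()].
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  vol <- gray_volume(array(as.integer(mask$voxels), dim(mask$voxels)),
                     scale_max = 1L)
  save_volume(vol, path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  vol <- load_volume(path, scale_max = 1L)
  if (any(!vol$voxels %in% c(0L, 1L)))
    stop("load_mask: file contains values other than 0/1")
  binary_mask(vol$voxels == 1L)
}
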