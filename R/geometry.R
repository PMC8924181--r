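#' Voxel geometry of an axial slice stack
#'
#' Records in-plane spacing, slice thickness and the inter-slice gap of a
#' 2D-axial multi-slice acquisition. Volume conversions use the slice
#' thickness only; the gap is carried for transparency but does not enter
#' the per-voxel volume (see the methods vignette).
#'
#' @param in_plane_spacing_mm numeric length-2, row/column spacing in mm.
#' @param slice_thickness_mm positive slice thickness in mm.
#' @param inter_slice_gap_mm non-negative gap between slices in mm.
#' @return An object of class `volume_geometry`.
#' @examples
#' g <- volume_geometry(c(0.4297, 0.4297), 5, 1)
#' voxel_volume_mm3(g)
#' @export
volume_geometry <- function(in_plane_spacing_mm = c(0.4297, 0.4297),
                            slice_thickness_mm = 5,
                            inter_slice_gap_mm = 1) {
  in_plane_spacing_mm <- as.numeric(in_plane_spacing_mm)
  if (length(in_plane_spacing_mm) == 1L)
    in_plane_spacing_mm <- rep(in_plane_spacing_mm, 2L)
  stopifnot(length(in_plane_spacing_mm) == 2L,
            all(in_plane_spacing_mm > 0),
            is.numeric(slice_thickness_mm), slice_thickness_mm > 0,
            is.numeric(inter_slice_gap_mm), inter_slice_gap_mm >= 0)
  structure(list(in_plane_spacing_mm = in_plane_spacing_mm,
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 inter_slice_gap_mm = as.numeric(inter_slice_gap_mm)),
            class = "volume_geometry")
}

#' @rdname volume_geometry
#' @param geometry a `volume_geometry`.
#' @export
voxel_volume_mm3 <- function(geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  prod(geometry$in_plane_spacing_mm) * geometry$slice_thickness_mm
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("volume_geometry: %.4f x %.4f x %g mm (gap %g mm), voxel %.5f mm^3\n",
              x$in_plane_spacing_mm[1], x$in_plane_spacing_mm[2],
              x$slice_thickness_mm, x$inter_slice_gap_mm,
              voxel_volume_mm3(x)))
  invisible(x)
}

#' Grayscale slice-stack volume
#'
#' A stack of axial slices of non-negative integer intensities with voxel
#' geometry, stored as a `[row, col, slice]` array.
#'
#' @param voxels 3D numeric array of non-negative integers (a matrix is
#'   promoted to a single slice).
#' @param geometry a [volume_geometry()].
#' @param scale_max native dynamic range (default 65535, i.e. 16 bit).
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(voxels, geometry = volume_geometry(),
                        scale_max = 65535L) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            dim(voxels)[3] >= 1L)
  v <- as.numeric(voxels)
  if (anyNA(v) || any(v < 0) || any(v != floor(v)))
    stop("gray_volume: intensities must be non-negative integers")
  if (any(v > scale_max))
    stop("gray_volume: intensities exceed scale_max")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, geometry = geometry,
                 scale_max = as.integer(scale_max)),
            class = "gray_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("gray_volume: %d x %d x %d slices, scale_max %d, range [%d, %d]\n",
              d[1], d[2], d[3], x$scale_max,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.gray_volume <- function(x) dim(x$voxels)

#' Binary mask congruent with a volume
#'
#' @param voxels 3D logical array (matrix promoted to one slice); numeric
#'   input is coerced with values restricted to 0/1.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!is.logical(voxels)) {
    v <- as.numeric(voxels)
    if (any(!v %in% c(0, 1))) stop("binary_mask: values must be 0/1")
    voxels <- array(v == 1, dim(voxels))
  }
  structure(list(voxels = voxels), class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$voxels)

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_mask: %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

check_congruent <- function(a, b) {
  da <- if (inherits(a, c("gray_volume", "binary_mask"))) dim(a$voxels) else dim(a)
  db <- if (inherits(b, c("gray_volume", "binary_mask"))) dim(b$voxels) else dim(b)
  if (!identical(da, db))
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}

#' Mask volume in millilitres
#'
#' Lesion load in mL: foreground voxel count times the per-voxel volume
#' (in-plane spacing squared times slice thickness), divided by 1000.
#'
#' @param mask a [binary_mask()].
#' @param geometry a [volume_geometry()].
#' @return Volume in mL.
#' @examples
#' m <- binary_mask(array(TRUE, c(10, 10, 10)))
#' mask_volume_ml(m, volume_geometry(c(0.4297, 0.4297), 5, 1))
#' @export
mask_volume_ml <- function(mask, geometry) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * voxel_volume_mm3(geometry) / 1000
}
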