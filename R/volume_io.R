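# Voxel containers and NIfTI plumbing.
#
# Measurement is grid-native: the affine is carried opaquely for round-trips
# but never interpreted; indices are 0-based half-open ranges throughout.

#' Voxel volume container
#'
#' Wraps a 3D intensity array with its voxel spacing (mm per edge, per axis)
#' and opaque affine metadata. All fracvox measurements operate on the raw
#' grid; orientation is never interpreted.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine optional 4x4 affine carried through I/O unchanged.
#' @return An object of class `voxel_volume` with fields `data`, `spacing`,
#'   `affine`.
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as_array3d(data, "volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel edge lengths (mm)")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "voxel_volume")
}

#' Binary segmentation mask container
#'
#' @param data 3D array coercible to 0/1 occupancy.
#' @param spacing,affine as [voxel_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as_array3d(data, "mask")
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1)))
    stop("mask values must be 0/1; use binarize_mask() for label images")
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel edge lengths (mm)")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "binary_mask")
}

as_array3d <- function(x, what) {
  if (is.null(dim(x))) stop(sprintf("%s must be a 3D array", what))
  d <- dim(x)
  if (length(d) == 4 && d[4] == 1) { dim(x) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3)
    stop(sprintf("%s must be 3D, got a %dD array (dims %s)",
                 what, length(d), paste(d, collapse = "x")))
  if (any(!is.finite(x))) stop(sprintf("%s contains non-finite values", what))
  x <- unclass(x)
  attributes(x) <- list(dim = d)
  x
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, spacing %s mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d occupied (%.3g cm^3)\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$data), mask_volume_cm3(x)))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path readable NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A [voxel_volume()]; intensities are unmodified, spacing taken from
#'   the header, affine carried opaquely.
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) { img <- array(as.numeric(img), d[1:3]); d <- dim(img) }
  if (length(d) != 3)
    stop(sprintf("expected a 3D NIfTI volume, got %dD (dims %s) in %s",
                 length(d), paste(d, collapse = "x"), path))
  sp <- attr(RNifti::pixdim(img), "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- as.numeric(sp)[seq_len(3)]
  aff <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  voxel_volume(array(as.numeric(img), d), spacing = sp, affine = aff)
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [voxel_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(x, path) {
  stopifnot(inherits(x, "voxel_volume") || inherits(x, "binary_mask"))
  img <- RNifti::asNifti(array(as.numeric(x$data), dim(x$data)))
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask
#'
#' Loads a volume and binarizes it (`> threshold`), collapsing multi-label
#' segmentations to a single ROI.
#'
#' @inheritParams load_volume
#' @param threshold binarization cut; voxels strictly above become occupied.
#' @return A [binary_mask()].
#' @export
load_mask <- function(path, threshold = 0) {
  binarize_mask(load_volume(path), threshold = threshold)
}

#' Binarize an intensity or label volume
#'
#' @param volume a [voxel_volume()] or 3D array.
#' @param threshold voxels with value strictly greater become occupied.
#' @return A [binary_mask()] with the volume's spacing.
#' @export
binarize_mask <- function(volume, threshold = 0) {
  if (inherits(volume, "voxel_volume")) {
    occ <- volume$data > threshold
    sp <- volume$spacing; aff <- volume$affine
  } else {
    occ <- as_array3d(volume, "volume") > threshold
    sp <- c(1, 1, 1); aff <- NULL
  }
  if (!any(occ)) stop("binarization produced an empty mask")
  binary_mask(array(as.integer(occ), dim(occ)), spacing = sp, affine = aff)
}

#' Tight bounding box of a mask
#'
#' @param mask a [binary_mask()] (or 0/1 array).
#' @param pad non-negative padding in voxels, clipped to the grid.
#' @return 3x2 integer matrix of 0-based half-open index ranges
#'   (rows = axes, columns = `lo`, `hi`).
#' @export
roi_bounding_box <- function(mask, pad = 0) {
  a <- mask_data(mask)
  if (!any(a > 0)) stop("mask is empty")
  stopifnot(pad >= 0)
  d <- dim(a)
  box <- matrix(NA_integer_, 3, 2, dimnames = list(NULL, c("lo", "hi")))
  for (ax in 1:3) {
    occ <- apply(a > 0, ax, any)
    idx <- which(occ)
    box[ax, ] <- c(max(0L, min(idx) - 1L - pad), min(d[ax], max(idx) + pad))
  }
  storage.mode(box) <- "integer"
  box
}

#' Crop to an index box
#'
#' @param x array, [voxel_volume()] or [binary_mask()].
#' @param box 3x2 matrix of 0-based half-open ranges, as from
#'   [roi_bounding_box()].
#' @return Same type as `x`, cropped.
#' @export
crop_to_box <- function(x, box) {
  sel <- lapply(1:3, function(ax) seq.int(box[ax, 1] + 1L, box[ax, 2]))
  if (inherits(x, "voxel_volume"))
    return(voxel_volume(x$data[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
                        x$spacing, x$affine))
  if (inherits(x, "binary_mask"))
    return(binary_mask(x$data[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
                       x$spacing, x$affine))
  x[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
}

#' Physical mask volume in cm^3
#'
#' Occupied-voxel count times the voxel volume (product of spacings, mm^3),
#' divided by 1000.
#'
#' @param mask a [binary_mask()].
#' @return Volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n <- sum(mask$data)
  if (n == 0) stop("mask is empty")
  n * prod(mask$spacing) / 1000
}

#' Check that a volume and mask share a grid
#'
#' Shapes must match exactly and spacings agree to 6 decimals; no resampling
#' is performed (harmonization belongs upstream).
#'
#' @param volume a [voxel_volume()].
#' @param mask a [binary_mask()].
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
check_grid_compatible <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop(sprintf("grid mismatch: volume %s vs mask %s",
                 paste(dim(volume$data), collapse = "x"),
                 paste(dim(mask$data), collapse = "x")))
  if (any(abs(volume$spacing - mask$spacing) > 1e-6))
    stop("spacing mismatch between volume and mask")
  invisible(TRUE)
}

# plain 0/1 array from mask-ish input
mask_data <- function(x) {
  if (inherits(x, "binary_mask")) return(x$data)
  if (inherits(x, "voxel_volume")) stop("expected a mask, got an intensity volume")
  a <- x
  if (is.logical(a)) { a <- array(as.integer(a), dim(a)) }
  if (is.null(dim(a))) stop("mask must be an array")
  a
}
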