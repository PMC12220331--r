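#' Define a voxel grid
#'
#' A `volume_grid` describes the shared sampling lattice every volume in an
#' analysis must live on: integer dimensions, voxel edge lengths in mm, and a
#' 4x4 affine mapping 0-based voxel indices to world coordinates in mm. No
#' resampling is ever performed by this package: mixing grids is a hard error.
#'
#' @param dims Integer vector of length 3, voxels per axis (each >= 8).
#' @param voxel_size_mm Positive numeric vector of length 3, mm per voxel.
#' @param affine Optional 4x4 matrix; defaults to a diagonal scaling by
#'   `voxel_size_mm` with the origin at voxel (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(c(40, 48, 40), c(2, 2, 2))
#' voxel_volume_mm3(g)
volume_grid <- function(dims, voxel_size_mm = c(2, 2, 2), affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, length(voxel_size_mm) == 3)
  if (any(dims < 8L)) {
    stop("grid too small: all dimensions must be >= 8 voxels", call. = FALSE)
  }
  if (any(voxel_size_mm <= 0)) {
    stop("voxel sizes must be positive", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("grid affine must be invertible", call. = FALSE)
  }
  structure(
    list(dims = dims, voxel_size_mm = as.numeric(voxel_size_mm),
         affine = affine),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %s mm\n",
              paste(x$dims, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param grid A `volume_grid`.
#' @return Scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size_mm)

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    isTRUE(all.equal(a$affine, b$affine))
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(grid_of(a), grid_of(b))) {
    stop("grid mismatch between ", what,
         "; all inputs must share one voxel grid (no resampling is done)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a brain volume
#'
#' A scalar 3-D field (PET uptake, T-scores, ...) on a `volume_grid`.
#'
#' @param values Numeric 3-D array matching `grid$dims`.
#' @param grid A `volume_grid`.
#' @return An object of class `brain_volume` with elements `values`, `grid`.
#' @export
brain_volume <- function(values, grid) {
  values <- as.array(values)
  stopifnot(identical(dim(values), as.integer(grid$dims)))
  structure(list(values = values, grid = grid), class = "brain_volume")
}

#' Construct a binary region mask
#'
#' @param inside Logical 3-D array matching `grid$dims`.
#' @param grid A `volume_grid`.
#' @param provenance Short string describing how the mask was made.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(inside, grid, provenance = "mask") {
  inside <- array(as.logical(inside), dim = grid$dims)
  structure(list(inside = inside, grid = grid, provenance = provenance),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s: %d voxels (%.1f mm^3)\n", x$provenance,
              sum(x$inside), sum(x$inside) * voxel_volume_mm3(x$grid)))
  invisible(x)
}

#' @export
print.brain_volume <- function(x, ...) {
  r <- range(x$values, na.rm = TRUE)
  cat(sprintf("<brain_volume> %s voxels, range [%.4g, %.4g]\n",
              paste(x$grid$dims, collapse = "x"), r[1], r[2]))
  invisible(x)
}

grid_of <- function(x) {
  if (inherits(x, "volume_grid")) return(x)
  if (!is.null(x$grid)) return(x$grid)
  stop("object carries no volume_grid", call. = FALSE)
}

mask_count <- function(mask) sum(mask$inside)

#' Read a NIfTI volume from disk
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as_mask Logical; return a `region_mask` (values > 0.5) instead of a
#'   `brain_volume`.
#' @return A `brain_volume` or `region_mask` on the grid described by the
#'   NIfTI header.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  grid <- volume_grid(dim(arr), abs(pd[1:3]),
                      affine = structure(RNifti::xform(img), dim = c(4, 4)))
  if (as_mask) {
    region_mask(arr > 0.5, grid, provenance = basename(path))
  } else {
    brain_volume(arr, grid)
  }
}

#' Write a volume or mask to NIfTI-1
#'
#' Masks are written as 0/1 integers. Writing is deterministic: the same
#' object always produces a byte-identical file (use uncompressed `.nii` if
#' byte-identity matters; gzip embeds metadata).
#'
#' @param x A `brain_volume` or `region_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "region_mask")) x$inside * 1L else x$values
  grid <- grid_of(x)
  img <- RNifti::asNifti(array(arr, dim = grid$dims))
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Ellipsoidal brain mask for a grid
#'
#' The synthetic "whole brain": an axis-aligned ellipsoid centred on the grid
#' with semi-axes 0.47 of each extent, mirror-symmetric across the x midline.
#'
#' @param grid A `volume_grid`.
#' @return A `region_mask`.
#' @export
brain_mask_for_grid <- function(grid) {
  d <- grid$dims
  ctr <- (d - 1) / 2
  semi <- 0.47 * d
  ii <- voxel_index_arrays(d)
  inside <- ((ii$x - ctr[1]) / semi[1])^2 +
    ((ii$y - ctr[2]) / semi[2])^2 +
    ((ii$z - ctr[3]) / semi[3])^2 <= 1
  region_mask(inside, grid, provenance = "brain")
}

# 0-based voxel index arrays, recycled to full grid shape
voxel_index_arrays <- function(d) {
  list(
    x = array(rep(seq_len(d[1]) - 1L, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]), dim = d),
    z = array(rep(seq_len(d[3]) - 1L, each = d[1] * d[2]), dim = d)
  )
}

# ellipsoid mask in voxel space (0-based centre, semi-axes in voxels)
ellipsoid_mask <- function(grid, center_vox, semi_vox) {
  ii <- voxel_index_arrays(grid$dims)
  inside <- ((ii$x - center_vox[1]) / semi_vox[1])^2 +
    ((ii$y - center_vox[2]) / semi_vox[2])^2 +
    ((ii$z - center_vox[3]) / semi_vox[3])^2 <= 1
  region_mask(inside, grid, provenance = "ellipsoid")
}

# 6-connected binary dilation by one voxel
dilate1 <- function(mask) {
  a <- mask$inside
  d <- dim(a)
  out <- a
  out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
  out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
  out[, , -1] <- out[, , -1] | a[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
  region_mask(out, mask$grid, provenance = paste0(mask$provenance, "+1vox"))
}

# centroid of a mask in 0-based voxel coordinates
mask_centroid_vox <- function(mask) {
  ii <- voxel_index_arrays(grid_of(mask)$dims)
  w <- mask$inside
  n <- sum(w)
  if (n == 0) stop("empty mask has no centroid", call. = FALSE)
  c(sum(ii$x[w]), sum(ii$y[w]), sum(ii$z[w])) / n
}
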