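#' Atlas label codes
#'
#' Integer codes used by the synthetic motor atlas: background, left/right
#' Rolandic strip (pre/postcentral cortex around the central sulcus),
#' left/right hand-knob, left/right paracentral lobule.
#'
#' @format Named integer vector.
#' @export
atlas_labels <- c(
  background   = 0L,
  rolandic_L   = 1L, rolandic_R   = 2L,
  handknob_L   = 3L, handknob_R   = 4L,
  paracentral_L = 5L, paracentral_R = 6L
)

#' Build the synthetic motor-cortex label atlas
#'
#' Constructs a label phantom with seven labels on the given grid: a
#' Rolandic strip per hemisphere with the hand-knob (lateral convexity) and
#' paracentral lobule (medial wall) carved out as separate labels inside the
#' strip's spatial extent. Regions are defined in fractional grid
#' coordinates on the left hemisphere and mirrored voxel-for-voxel across
#' the x midline, so the atlas is exactly mirror-symmetric.
#'
#' @param grid A `volume_grid`. Must be large enough that every region keeps
#'   at least a handful of voxels after intersection with the brain mask.
#' @return A `label_atlas`: list with integer array `labels`, `grid`, and a
#'   `legend` mapping names to codes.
#' @export
#' @examples
#' atlas <- build_atlas_phantom(volume_grid(c(40, 48, 40)))
#' table(atlas$labels)
build_atlas_phantom <- function(grid) {
  d <- grid$dims
  brain <- brain_mask_for_grid(grid)$inside
  labels <- array(0L, dim = d)

  # fractional boxes [xlo,xhi] x [ylo,yhi] x [zlo,zhi] on the LEFT hemisphere
  box_idx <- function(fr, n) {
    lo <- floor(fr[1] * n)
    hi <- ceiling(fr[2] * n) - 1
    seq.int(max(0, lo), min(n - 1, hi)) + 1L   # 1-based for indexing
  }
  left_half <- seq_len(floor(d[1] / 2))
  fill_box <- function(labels, fx, fy, fz, code) {
    xs <- intersect(box_idx(fx, d[1]), left_half)
    ys <- box_idx(fy, d[2])
    zs <- box_idx(fz, d[3])
    labels[xs, ys, zs] <- code
    labels
  }
  labels <- fill_box(labels, c(0.10, 0.475), c(0.50, 0.625), c(0.55, 0.875),
                     atlas_labels[["rolandic_L"]])
  labels <- fill_box(labels, c(0.15, 0.325), c(0.52, 0.605), c(0.64, 0.82),
                     atlas_labels[["handknob_L"]])
  labels <- fill_box(labels, c(0.40, 0.475), c(0.51, 0.615), c(0.66, 0.86),
                     atlas_labels[["paracentral_L"]])
  labels[!brain] <- 0L

  # mirror left labels onto the right hemisphere: x -> dims_x - 1 - x
  mirrored <- labels[d[1]:1, , ]
  right <- mirrored > 0L
  labels[right] <- mirrored[right] + 1L   # L codes are odd, R = L + 1

  counts <- table(factor(labels[labels > 0L],
                         levels = atlas_labels[atlas_labels > 0L]))
  if (any(counts < 8)) {
    stop("grid too small to place all atlas regions (under 8 voxels: ",
         paste(names(counts)[counts < 8], collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(labels = labels, grid = grid, legend = atlas_labels),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("<label_atlas>", paste(x$grid$dims, collapse = "x"), "voxels\n")
  nz <- x$legend[x$legend > 0]
  for (nm in names(nz)) {
    cat(sprintf("  %-14s %d voxels\n", nm, sum(x$labels == nz[[nm]])))
  }
  invisible(x)
}

#' Extract an atlas region as a mask
#'
#' `name` may be a single label name from the legend or a bilateral
#' shorthand: `"handknob"` / `"paracentral"` (union of left and right) or
#' `"rolandic"`, the whole Rolandic area — both strips together with the
#' hand-knob and paracentral sublabels carved out of them, which
#' anatomically belong to the pre/postcentral cortex.
#'
#' @param atlas A `label_atlas`.
#' @param name Region name.
#' @return A `region_mask`.
#' @export
label_mask <- function(atlas, name) {
  legend <- atlas$legend
  if (name == "rolandic") {
    codes <- legend[legend > 0]
  } else if (name %in% c("handknob", "paracentral")) {
    codes <- legend[paste0(name, c("_L", "_R"))]
  } else if (name %in% names(legend) && name != "background") {
    codes <- legend[[name]]
  } else {
    stop("unknown atlas label '", name, "'; legend has: ",
         paste(setdiff(names(legend), "background"), collapse = ", "),
         call. = FALSE)
  }
  region_mask(atlas$labels %in% codes, atlas$grid, provenance = name)
}

#' Region sizes of an atlas
#'
#' @param atlas A `label_atlas`.
#' @return A tibble with `region`, `n_voxels`, `volume_mm3`.
#' @export
atlas_region_sizes <- function(atlas) {
  nz <- atlas$legend[atlas$legend > 0]
  tibble::tibble(
    region = names(nz),
    n_voxels = vapply(nz, function(code) sum(atlas$labels == code), 0L),
    volume_mm3 = n_voxels * voxel_volume_mm3(atlas$grid)
  )
}
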