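# Sphere-shaped 3D ROIs in physical millimetres on anisotropic voxel grids.
#
# Coordinate convention (used consistently by mask construction, value
# extraction and the texture neighbourhoods): voxel indices are 1-based in R;
# the physical centre of voxel (i, j, k) is ((i-1)*sx, (j-1)*sy, (k-1)*sz),
# i.e. the grid origin sits at the centre of voxel (1,1,1).

#' Spherical ROI specification
#'
#' @param center Physical centre, mm triple.
#' @param diameter Sphere diameter in mm (> 0). The study sizes are 10, 20
#'   and 30 mm, but any positive diameter is accepted.
#' @return An object of class `sphere_roi`.
#' @export
sphere_roi <- function(center, diameter) {
  stopifnot(length(center) == 3L, all(is.finite(center)))
  if (!(diameter > 0)) .stopf("diameter must be > 0")
  structure(list(center = as.numeric(center), diameter = as.numeric(diameter)),
            class = "sphere_roi")
}

#' Rasterize a spherical ROI onto a voxel grid
#'
#' A voxel is included iff the Euclidean *physical* distance from its centre
#' to the sphere centre is at most `diameter / 2`; boundary ties are
#' included. Working in mm (never index space) is essential on these grids,
#' where the slice spacing (5.5 or 6.6 mm) is about five times the in-plane
#' spacing. The rule is deterministic, so masks of increasing diameter at a
#' fixed centre are strictly nested.
#'
#' @param spacing Voxel spacing, mm triple.
#' @param shape Grid dimensions, voxel triple.
#' @param roi A [sphere_roi()].
#' @return An object of class `roi_mask`: list with `mask` (logical 3D
#'   array), `spacing`, `source` (the ROI) and `voxel_count`.
#' @examples
#' m <- sphere_mask(c(1.125, 1.125, 5.5), c(48, 48, 12),
#'                  sphere_roi(c(26, 26, 27.5), 30))
#' m$voxel_count
#' @export
sphere_mask <- function(spacing, shape, roi) {
  stopifnot(inherits(roi, "sphere_roi"), length(spacing) == 3L,
            length(shape) == 3L)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  r <- roi$diameter / 2
  for (ax in 1:3) {
    lo <- -spacing[ax] / 2
    hi <- (shape[ax] - 1) * spacing[ax] + spacing[ax] / 2
    if (roi$center[ax] - r < lo || roi$center[ax] + r > hi)
      .stopf("sphere (centre %.4g mm, radius %.4g mm) exceeds the grid along axis %d [%.4g, %.4g] mm",
             roi$center[ax], r, ax, lo, hi)
  }
  d2 <- lapply(1:3, function(ax)
    (seq.int(0L, shape[ax] - 1L) * spacing[ax] - roi$center[ax])^2)
  dist2 <- outer(outer(d2[[1L]], d2[[2L]], `+`), d2[[3L]], `+`)
  mask <- dist2 <= r * r + 1e-9  # tiny slack keeps exact-boundary ties in
  vc <- sum(mask)
  if (vc < 1L) .stopf("empty ROI mask: diameter %.4g mm resolves no voxel", roi$diameter)
  structure(list(mask = mask, spacing = spacing, source = roi,
                 voxel_count = as.integer(vc)),
            class = "roi_mask")
}

#' Place an ROI centre in a volume
#'
#' The default `"centroid"` rule puts the centre at the volume's physical
#' centroid snapped to the nearest voxel centre. The rule does not depend on
#' the diameter, so the three study diameters share one centre per
#' subject/sequence volume — mirroring identical ROI placement across sizes
#' within a sequence. Centres are recomputed per sequence volume, never
#' copied between sequences.
#'
#' @param volume A [subject_volume()].
#' @param diameter Optional diameter in mm; when given, the fitted sphere is
#'   checked against the grid.
#' @param rule Placement rule; only `"centroid"` is implemented.
#' @return A [sphere_roi()] when `diameter` is given, otherwise the centre
#'   as a mm triple.
#' @export
place_center <- function(volume, diameter = NULL, rule = c("centroid")) {
  stopifnot(inherits(volume, "subject_volume"))
  rule <- match.arg(rule)
  d <- dim(volume$voxels)
  idx <- round((d - 1) / 2)
  center <- idx * volume$spacing
  if (is.null(diameter)) return(center)
  roi <- sphere_roi(center, diameter)
  sphere_mask(volume$spacing, d, roi)  # errors if it does not fit
  roi
}

#' Extract the intensity sample under an ROI mask
#'
#' Returns the voxel values under the mask together with their 1-based
#' integer voxel coordinates (the texture-matrix builders need the spatial
#' arrangement, not just the values). Values and coordinates are in the same
#' (column-major) order.
#'
#' @param volume A [subject_volume()].
#' @param mask An [sphere_mask()] result congruent with `volume` (same grid
#'   shape and spacing).
#' @return List with `values` (numeric vector of length `voxel_count`) and
#'   `coords` (integer matrix, `voxel_count` x 3).
#' @export
extract_roi_values <- function(volume, mask) {
  stopifnot(inherits(volume, "subject_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$voxels), dim(mask$mask)))
    .stopf("mask shape (%s) does not match volume shape (%s)",
           paste(dim(mask$mask), collapse = "x"),
           paste(dim(volume$voxels), collapse = "x"))
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9)
    .stopf("mask spacing does not match volume spacing")
  list(values = volume$voxels[mask$mask],
       coords = which(mask$mask, arr.ind = TRUE))
}
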