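#' Grid geometry of a co-registered volume
#'
#' A `grid_geometry` records the voxel grid (`shape`) and the 4x4 affine that
#' maps 0-based voxel indices to world millimetre coordinates in RAS+
#' orientation (world x > 0 is the right hemisphere). All volumes in a cohort
#' must share one geometry; the pipeline never resamples.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param affine Numeric 4x4 matrix, 0-based voxel index -> world mm (RAS+).
#' @return An object of class `grid_geometry` with fields `shape`, `affine`
#'   and `voxel_volume_mm3` (absolute determinant of the upper-left 3x3 block).
#' @export
grid_geometry <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be 3 positive integers", call. = FALSE)
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  rot <- affine[1:3, 1:3]
  det3 <- det(rot)
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps) {
    stop("affine upper-left 3x3 block must be invertible", call. = FALSE)
  }
  structure(
    list(shape = shape, affine = affine, voxel_volume_mm3 = abs(det3)),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("<grid_geometry> ", paste(x$shape, collapse = " x "),
      " voxels, ", format(x$voxel_volume_mm3, digits = 4), " mm^3/voxel\n",
      sep = "")
  invisible(x)
}

#' Default centred isotropic geometry
#'
#' Convenience constructor: isotropic voxels with the world origin at the grid
#' centre, axes aligned with RAS+. Used by the synthetic cohort generator.
#'
#' @param shape Integer vector of length 3.
#' @param voxel_size_mm Positive scalar edge length.
#' @return A `grid_geometry`.
#' @export
centered_geometry <- function(shape, voxel_size_mm) {
  stopifnot(voxel_size_mm > 0)
  shape <- as.integer(shape)
  aff <- diag(c(rep(voxel_size_mm, 3L), 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * voxel_size_mm
  grid_geometry(shape, aff)
}

#' Convert 0-based voxel indices to world coordinates
#'
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices, or a length-3
#'   vector.
#' @param geometry A `grid_geometry`.
#' @return Numeric matrix (n x 3) of world mm coordinates.
#' @export
voxel_to_world <- function(ijk, geometry) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  ijk <- cbind(ijk, 1)
  out <- ijk %*% t(geometry$affine)
  out[, 1:3, drop = FALSE]
}

#' World coordinates of every voxel centre along one axis
#'
#' For axis-aligned affines this gives the per-slice world coordinate; used to
#' assign hemispheres cheaply.
#' @keywords internal
axis_world_coords <- function(geometry, axis = 1L) {
  n <- geometry$shape[axis]
  ijk <- matrix(0, n, 3)
  ijk[, axis] <- seq_len(n) - 1
  voxel_to_world(ijk, geometry)[, axis]
}

#' Hemisphere of voxels by world x coordinate
#'
#' Voxels with world x beyond +half a voxel are `right`, beyond -half a voxel
#' `left`, and `midline` within the central band. Follows the RAS+ convention
#' in which positive x is the anatomical right.
#'
#' @param ijk 0-based voxel index matrix (n x 3) or length-3 vector.
#' @param geometry A `grid_geometry`.
#' @return Character vector in `c("left", "right", "midline")`.
#' @export
hemisphere_of <- function(ijk, geometry) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  if (any(ijk < 0) || any(ijk >= matrix(geometry$shape, nrow(ijk), 3, byrow = TRUE))) {
    stop("voxel index out of range for this geometry", call. = FALSE)
  }
  x <- voxel_to_world(ijk, geometry)[, 1]
  half <- voxel_size_x(geometry) / 2
  ifelse(x > half, "right", ifelse(x < -half, "left", "midline"))
}

# Edge length along world x implied by the affine's first column.
voxel_size_x <- function(geometry) {
  sqrt(sum(geometry$affine[1:3, 1]^2))
}

# TRUE if two geometries agree: identical shapes, affines within `tol` mm
# per entry. Masks are assumed pre-registered, so shapes must match exactly.
same_geometry <- function(g1, g2, tol = 1e-4) {
  identical(g1$shape, g2$shape) && all(abs(g1$affine - g2$affine) <= tol)
}

stopifnot_same_geometry <- function(g1, g2, what = "volumes") {
  if (!same_geometry(g1, g2)) {
    stop("alignment error: ", what, " do not share one grid geometry",
         call. = FALSE)
  }
  invisible(TRUE)
}
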