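#' Forward projection (the system operator A)
#'
#' Computes the line integral of the attenuation volume along every
#' source--detector ray: `proj[a, p]` is the integral for view angle `a`
#' and detector pixel `p`, in attenuation-length units (dimensionless when
#' the volume is in 1/mm and distances in mm).  The map is linear in the
#' volume and shares its intersection weights with [back_project()], so
#' the pair is an exact adjoint.
#'
#' @param vol attenuation volume: a matrix (2D modes) or 3D array matching
#'   `geom$volume_shape`, values in 1/mm.
#' @param geom a [scan_geometry()].
#' @param angle_idx optional 1-based indices restricting the projection to
#'   a subset of views (rows of the result follow this order).
#' @return matrix of line integrals, `length(angle_idx)` x
#'   `prod(detector_pixel_counts)`.  Cone-beam detector pixels are
#'   flattened column-major (u fastest).
#' @seealso [back_project()], [sart_weights()]
#' @export
forward_project <- function(vol, geom, angle_idx = NULL) {
  stopifnot(inherits(geom, "scan_geometry"))
  check_volume(vol, geom)
  if (is.null(angle_idx)) angle_idx <- seq_along(geom$angles)
  cpp_forward(as.numeric(vol), geom_clist(geom), as.integer(angle_idx) - 1L)
}

#' Back projection (the adjoint operator A^T)
#'
#' Spreads projection values back along their rays with the same
#' intersection lengths used by [forward_project()]:
#' \eqn{\langle Ax, y\rangle = \langle x, A^T y\rangle} holds to rounding.
#'
#' @param proj projection matrix, rows matching `angle_idx` (all angles by
#'   default), columns the detector pixels.
#' @inheritParams forward_project
#' @return volume-shaped array.
#' @export
back_project <- function(proj, geom, angle_idx = NULL) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (is.null(angle_idx)) {
    check_projections(proj, geom)
    angle_idx <- seq_along(geom$angles)
  } else {
    if (!is.matrix(proj) || nrow(proj) != length(angle_idx) ||
        ncol(proj) != n_detector_pixels(geom) || !all(is.finite(proj)))
      stop("'proj' must be a finite length(angle_idx) x n_det matrix")
  }
  v <- cpp_back(proj, geom_clist(geom), as.integer(angle_idx) - 1L)
  array(v, dim = geom$volume_shape)
}

#' SART weighting sums
#'
#' Row sums (per-ray total intersection length, the diagonal of `W^{-1}`)
#' and column sums (per-voxel total intersection length, the diagonal of
#' `V`) of the system matrix, optionally restricted to a subset of view
#' angles as used by per-angle SART sweeps.
#'
#' @inheritParams forward_project
#' @return list with `row_sums` (matrix, angles x detector pixels) and
#'   `col_sums` (volume-shaped array); all entries are nonnegative.
#' @export
sart_weights <- function(geom, angle_idx = NULL) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (is.null(angle_idx)) angle_idx <- seq_along(geom$angles)
  w <- cpp_weights(geom_clist(geom), as.integer(angle_idx) - 1L)
  w$col_sums <- array(w$col_sums, dim = geom$volume_shape)
  w
}
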