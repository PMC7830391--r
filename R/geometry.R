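#' Scan geometry for tomographic acquisition
#'
#' Describes the acquisition that defines the system operator \eqn{A}:
#' beam shape, source/detector distances, detector sampling, view angles
#' and the reconstruction voxel grid.  The operator itself is never
#' materialised; [forward_project()] and [back_project()] traverse rays on
#' demand with exact ray--voxel intersection lengths.
#'
#' Conventions: the volume is centred on the rotation axis, voxel centres
#' sit at \eqn{(i + 0.5 - n/2)\,\Delta} world coordinates (0-based index
#' \eqn{i}), and angles are degrees counter-clockwise from the +x axis.
#'
#' @param beam_mode one of `"parallel2d"`, `"fan2d"`, `"cone3d"`.
#' @param angles view angles in degrees (finite, distinct), e.g. from
#'   [make_angles()].
#' @param volume_shape integer vector of voxels per axis (length 2 for the
#'   2D modes, 3 for `cone3d`).
#' @param voxel_size voxel edge length in mm, recycled per axis.
#' @param detector_pixel_counts detector pixels per detector axis (length 1
#'   in 2D, 2 for `cone3d`).  Default: wide enough to cover the volume
#'   diagonal at the detector.
#' @param detector_pixel_pitch detector pixel pitch in mm per axis.
#' @param source_to_origin,source_to_detector source--rotation-axis and
#'   source--detector distances in mm (fan/cone only;
#'   `source_to_detector > source_to_origin`).
#' @return an object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry("fan2d", angles = make_angles(360, 50),
#'                    volume_shape = c(64, 64), voxel_size = 2.5)
#' g
#' @export
scan_geometry <- function(beam_mode = c("parallel2d", "fan2d", "cone3d"),
                          angles,
                          volume_shape,
                          voxel_size = 1,
                          detector_pixel_counts = NULL,
                          detector_pixel_pitch = NULL,
                          source_to_origin = NULL,
                          source_to_detector = NULL) {
  beam_mode <- match.arg(beam_mode)
  ndim <- if (beam_mode == "cone3d") 3L else 2L

  angles <- as.numeric(angles)
  if (length(angles) < 1L || anyNA(angles) || any(!is.finite(angles)))
    stop("'angles' must be a non-empty vector of finite angles (degrees)")
  if (anyDuplicated(angles))
    stop("'angles' must be distinct")

  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != ndim || any(volume_shape < 1L))
    stop(sprintf("'volume_shape' must be %d positive integers for %s",
                 ndim, beam_mode))
  voxel_size <- rep_len(as.numeric(voxel_size), ndim)
  if (any(voxel_size <= 0)) stop("'voxel_size' must be positive")

  ndet_axes <- if (beam_mode == "cone3d") 2L else 1L
  fov <- sqrt(sum((volume_shape * voxel_size)^2))
  if (is.null(detector_pixel_pitch)) detector_pixel_pitch <- min(voxel_size)
  detector_pixel_pitch <- rep_len(as.numeric(detector_pixel_pitch), ndet_axes)
  if (any(detector_pixel_pitch <= 0)) stop("'detector_pixel_pitch' must be positive")

  if (beam_mode == "parallel2d") {
    source_to_origin <- source_to_detector <- NA_real_
    mag <- 1
  } else {
    if (is.null(source_to_origin)) source_to_origin <- 2 * fov
    if (is.null(source_to_detector)) source_to_detector <- 4 * fov
    source_to_origin <- as.numeric(source_to_origin)
    source_to_detector <- as.numeric(source_to_detector)
    if (!is.finite(source_to_origin) || source_to_origin <= 0 ||
        !is.finite(source_to_detector) || source_to_detector <= 0)
      stop("source distances must be strictly positive")
    if (source_to_detector <= source_to_origin)
      stop("'source_to_detector' must exceed 'source_to_origin'")
    mag <- source_to_detector / source_to_origin
  }

  if (is.null(detector_pixel_counts)) {
    detector_pixel_counts <-
      rep_len(as.integer(ceiling(mag * fov / detector_pixel_pitch[1]) + 2L),
              ndet_axes)
  }
  detector_pixel_counts <- rep_len(as.integer(detector_pixel_counts), ndet_axes)
  if (any(detector_pixel_counts < 1L))
    stop("'detector_pixel_counts' must be >= 1")

  structure(
    list(beam_mode = beam_mode,
         source_to_origin = source_to_origin,
         source_to_detector = source_to_detector,
         detector_pixel_counts = detector_pixel_counts,
         detector_pixel_pitch = detector_pixel_pitch,
         angles = angles,
         volume_shape = volume_shape,
         voxel_size = voxel_size),
    class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s\n", x$beam_mode))
  cat(sprintf("  views     : %d angles in [%g, %g] deg\n",
              length(x$angles), min(x$angles), max(x$angles)))
  cat(sprintf("  volume    : %s voxels of %s mm\n",
              paste(x$volume_shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  cat(sprintf("  detector  : %s pixels, pitch %s mm\n",
              paste(x$detector_pixel_counts, collapse = "x"),
              paste(signif(x$detector_pixel_pitch, 4), collapse = "x")))
  if (x$beam_mode != "parallel2d")
    cat(sprintf("  distances : DSO %g mm, DSD %g mm\n",
                x$source_to_origin, x$source_to_detector))
  invisible(x)
}

#' Equally spaced view angles over a span
#'
#' `n_views` angles starting at `start` with increment
#' `span_degrees / n_views`; the end of the span is excluded (half-open),
#' so 50 views over 360 degrees are 7.2 degrees apart and 50 views over
#' 180 degrees are 3.6 degrees apart.
#'
#' @param span_degrees angular span in degrees (> 0).
#' @param n_views number of views (>= 1).
#' @param start first angle in degrees.
#' @return numeric vector of `n_views` angles in degrees.
#' @examples
#' diff(make_angles(360, 50))[1]  # 7.2
#' @export
make_angles <- function(span_degrees, n_views, start = 0) {
  if (!is.finite(span_degrees) || span_degrees <= 0)
    stop("'span_degrees' must be > 0")
  n_views <- as.integer(n_views)
  if (is.na(n_views) || n_views < 1L) stop("'n_views' must be >= 1")
  start + span_degrees / n_views * (seq_len(n_views) - 1)
}

n_detector_pixels <- function(geom) prod(geom$detector_pixel_counts)

#' Restrict a geometry to a subset of its view angles
#'
#' @param geom a [scan_geometry()].
#' @param idx integer indices into `geom$angles` (1-based, distinct).
#' @return a `scan_geometry` with only the selected angles.
#' @export
subset_angles <- function(geom, idx) {
  stopifnot(inherits(geom, "scan_geometry"))
  idx <- as.integer(idx)
  if (length(idx) < 1L || anyNA(idx) || any(idx < 1L) ||
      any(idx > length(geom$angles)) || anyDuplicated(idx))
    stop("'idx' must be distinct angle indices within range")
  geom$angles <- geom$angles[idx]
  geom
}

# Internal: geometry in the form the C++ traversal expects.
geom_clist <- function(geom) {
  mode <- match(geom$beam_mode, c("parallel2d", "fan2d", "cone3d")) - 1L
  list(mode = mode,
       dso = if (is.na(geom$source_to_origin)) 0 else geom$source_to_origin,
       dsd = if (is.na(geom$source_to_detector)) 0 else geom$source_to_detector,
       ndet = geom$detector_pixel_counts,
       dpitch = geom$detector_pixel_pitch,
       angles_rad = geom$angles * pi / 180,
       vshape = geom$volume_shape,
       vsize = geom$voxel_size)
}

check_volume <- function(vol, geom, arg = "vol") {
  dv <- dim(vol)
  if (is.null(dv)) dv <- length(vol)
  if (length(dv) != length(geom$volume_shape) ||
      !all(dv == geom$volume_shape))
    stop(sprintf("'%s' has shape [%s] but geometry expects [%s]",
                 arg, paste(dv, collapse = ","),
                 paste(geom$volume_shape, collapse = ",")))
  if (!all(is.finite(vol))) stop(sprintf("'%s' must be finite", arg))
  invisible(TRUE)
}

check_projections <- function(proj, geom, arg = "proj") {
  if (!is.matrix(proj))
    stop(sprintf("'%s' must be a matrix (angles x detector pixels)", arg))
  if (nrow(proj) != length(geom$angles) ||
      ncol(proj) != n_detector_pixels(geom))
    stop(sprintf("'%s' is %dx%d but geometry expects %dx%d",
                 arg, nrow(proj), ncol(proj),
                 length(geom$angles), n_detector_pixels(geom)))
  if (!all(is.finite(proj))) stop(sprintf("'%s' must be finite", arg))
  invisible(TRUE)
}
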