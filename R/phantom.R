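#' Piecewise-constant ellipse/ellipsoid phantom specification
#'
#' A phantom is a list of additive ellipse (2D) or ellipsoid (3D)
#' elements, each described in a normalised frame where the volume spans
#' \eqn{[-0.5, 0.5]} per axis: `center` and `semi_axes` are fractions of
#' the field of view, `rotation` is degrees counter-clockwise in the xy
#' plane, `intensity` is the additive attenuation contribution (1/mm,
#' may be negative for carve-outs as long as every voxel sums to >= 0).
#'
#' @param elements list of elements; each a list with fields `center`
#'   (length 2 or 3), `semi_axes` (same length, all > 0), `rotation`
#'   (degrees, default 0) and `intensity`.
#' @param grid_shape integer vector, voxels per axis.
#' @return object of class `phantom_spec`.
#' @seealso [render_phantom()], [thorax_phantom_spec()]
#' @export
phantom_spec <- function(elements, grid_shape) {
  grid_shape <- as.integer(grid_shape)
  if (!length(grid_shape) %in% 2:3 || any(grid_shape < 1L))
    stop("'grid_shape' must be 2 or 3 positive integers")
  ndim <- length(grid_shape)
  elements <- lapply(elements, function(el) {
    el$center <- rep_len(as.numeric(el$center), ndim)
    el$semi_axes <- rep_len(as.numeric(el$semi_axes), ndim)
    if (any(el$semi_axes <= 0)) stop("element semi-axes must be > 0")
    el$rotation <- if (is.null(el$rotation)) 0 else as.numeric(el$rotation)
    el$intensity <- as.numeric(el$intensity)
    if (!is.finite(el$intensity)) stop("element intensity must be finite")
    el
  })
  structure(list(elements = elements, grid_shape = grid_shape),
            class = "phantom_spec")
}

#' Rasterise a phantom specification
#'
#' Deterministic: a voxel's value is the sum of the intensities of every
#' element whose ellipse/ellipsoid contains the voxel centre.
#'
#' @param spec a [phantom_spec()].
#' @return attenuation array of shape `spec$grid_shape` (1/mm).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape
  ndim <- length(n)
  ax <- lapply(n, function(k) (seq_len(k) - 0.5) / k - 0.5)
  vol <- array(0, dim = n)
  if (ndim == 2L) {
    X <- matrix(ax[[1]], n[1], n[2])
    Y <- matrix(ax[[2]], n[1], n[2], byrow = TRUE)
  } else {
    X <- array(ax[[1]], dim = n)
    Y <- aperm(array(ax[[2]], dim = n[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(ax[[3]], dim = n[c(3, 1, 2)]), c(2, 3, 1))
  }
  for (el in spec$elements) {
    th <- el$rotation * pi / 180
    ct <- cos(th); st <- sin(th)
    dx <- X - el$center[1]; dy <- Y - el$center[2]
    u <- ( ct * dx + st * dy) / el$semi_axes[1]
    v <- (-st * dx + ct * dy) / el$semi_axes[2]
    q <- u^2 + v^2
    if (ndim == 3L) q <- q + ((Z - el$center[3]) / el$semi_axes[3])^2
    vol <- vol + el$intensity * (q <= 1)
  }
  if (any(vol < 0))
    stop("phantom spec yields negative attenuation; adjust element intensities")
  vol
}

#' Thorax-like phantom (anthropomorphic stand-in)
#'
#' A synthetic piecewise-constant attenuation map emulating a thorax
#' cross-section: an elliptical body outline, two low-attenuation lungs,
#' a heart-like blob, a posterior spine and rib features.  Intensities
#' are on a per-mm attenuation scale with all values in [0, 0.025].
#' This is a fully synthetic stand-in for anthropomorphic phantoms; it
#' reproduces their piecewise-constant, sharp-edged, low-contrast
#' character but none of their anatomy.
#'
#' Attenuation values are physically based for a ~70 keV beam: soft
#' tissue/water 0.019 per mm, inflated lung 0.005, blood-filled heart
#' 0.022, mineralised bone capped at the 0.025 ceiling.
#'
#' @param grid_shape voxels per axis (length 2 or 3); 3D variants extrude
#'   the slice along z with element-specific z half-heights.
#' @param variant `"training"`, `"male"` or `"female"`: the two test
#'   variants deterministically perturb element sizes and intensities to
#'   emulate differently parametrised samples of the same anatomy.
#' @return a [phantom_spec()].
#' @export
thorax_phantom_spec <- function(grid_shape = c(64, 64),
                                variant = c("training", "male", "female")) {
  variant <- match.arg(variant)
  # size / intensity perturbation factors per variant (deterministic)
  sz <- switch(variant, training = 1, male = 0.93, female = 1.08)
  it <- switch(variant, training = 1, male = 0.90, female = 0.82)
  ndim <- length(as.integer(grid_shape))
  z <- function(c2, a2, cz = 0, az = 0.45) {  # lift 2D element to 3D
    if (ndim == 2L) list(center = c2, semi_axes = a2)
    else list(center = c(c2, cz), semi_axes = c(a2, az))
  }
  el <- function(c2, a2, rot, int, cz = 0, az = 0.45) {
    e <- z(c2, a2 * sz, cz, az)
    e$rotation <- rot; e$intensity <- int * it
    e
  }
  elements <- list(
    el(c(0,  0.00), c(0.44, 0.34), 0,  0.019),               # body (water)
    el(c(-0.17, 0.02), c(0.15, 0.22), 10, -0.014, az = 0.35),# left lung
    el(c( 0.19, 0.02), c(0.14, 0.21), -8, -0.014, az = 0.35),# right lung
    el(c( 0.03, -0.02), c(0.10, 0.12), -25, 0.003, az = 0.25),# heart
    el(c(0, -0.27), c(0.045, 0.05), 0, 0.006, az = 0.40),    # spine
    el(c(-0.33, -0.12), c(0.025, 0.04), 35, 0.006),          # ribs
    el(c( 0.33, -0.12), c(0.025, 0.04), -35, 0.006),
    el(c(-0.30,  0.18), c(0.025, 0.04), -35, 0.006),
    el(c( 0.30,  0.18), c(0.025, 0.04), 35, 0.006)
  )
  phantom_spec(elements, grid_shape)
}
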