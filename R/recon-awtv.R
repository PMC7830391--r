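# Adaptive-weighted total variation: norm, smoothed gradient, descent.

# Apply a matrix operation along one axis of a 2D/3D array.
along_axis <- function(x, axis, f) {
  d <- dim(x)
  k <- length(d)
  perm <- c(axis, setdiff(seq_len(k), axis))
  y <- aperm(x, perm)
  dy <- dim(y)
  dim(y) <- c(dy[1], prod(dy[-1]))
  y <- f(y)
  dim(y) <- dy
  aperm(y, order(perm))
}

# Backward difference along `axis`, zero at the lower boundary.
bdiff <- function(x, axis) {
  x - along_axis(x, axis, function(m)
    m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE])
}

# Shift slices down by one along `axis` (value at v+e), zero at the top.
lead0 <- function(x, axis) {
  along_axis(x, axis, function(m)
    rbind(m[-1L, , drop = FALSE], matrix(0, 1L, ncol(m))))
}

#' Adaptive-weighted total variation norm
#'
#' \deqn{\|x\|_{AwTV} = \sum_v \sqrt{\sum_a w_a(v)\,\Delta_a(v)^2},\quad
#'       w_a(v) = e^{-(\Delta_a(v)/\delta)^2}}
#' where \eqn{\Delta_a} is the backward finite difference along axis
#' \eqn{a} (zero outside the grid).  Small local differences get weight
#' close to 1 (smoothed as in plain TV); differences large relative to
#' the scale factor \eqn{\delta} are down-weighted, preserving edges.
#' As \eqn{\delta \to \infty} the norm tends to the isotropic TV norm.
#'
#' @param x image array (matrix or 3D array).
#' @param delta edge-preservation scale factor (> 0), attenuation
#'   gradient units; see [estimate_delta()].
#' @return scalar norm value.
#' @export
awtv_norm <- function(x, delta) {
  if (!is.finite(delta) || delta <= 0) stop("'delta' must be > 0")
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
  acc <- 0
  for (a in seq_along(dim(x))) {
    d <- bdiff(x, a)
    acc <- acc + exp(-(d / delta)^2) * d^2
  }
  sum(sqrt(acc))
}

#' Gradient of the smoothed adaptive-weighted TV norm
#'
#' Analytic gradient of [awtv_norm()] with each square root smoothed to
#' \eqn{\sqrt{\cdot + \mu^2}} and the exponential weights treated as
#' frozen coefficients at the current image (a standard
#' lagged-diffusivity linearisation).  Finite everywhere.
#'
#' @inheritParams awtv_norm
#' @param mu smoothing constant; default `1e-8 * max(max(|x|), 1)`.
#' @return array of the same shape as `x`.
#' @export
awtv_gradient <- function(x, delta, mu = NULL) {
  if (!is.finite(delta) || delta <= 0) stop("'delta' must be > 0")
  if (is.null(mu)) mu <- 1e-8 * max(max(abs(x)), 1)
  if (!is.finite(mu) || mu <= 0) stop("'mu' must be > 0")
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
  axes <- seq_along(dim(x))
  d <- lapply(axes, function(a) bdiff(x, a))
  w <- lapply(d, function(di) exp(-(di / delta)^2))
  phi <- mu^2
  for (a in axes) phi <- phi + w[[a]] * d[[a]]^2
  phi <- sqrt(phi)
  g <- array(0, dim = dim(x))
  for (a in axes) {
    t_a <- w[[a]] * d[[a]] / phi
    g <- g + t_a - lead0(t_a, a)
  }
  g
}

#' Normalised steepest-descent TV minimisation phase
#'
#' `ng` sub-iterations of \eqn{x \leftarrow x - \eta\, s / \|s\|_2} with
#' \eqn{s} the smoothed AwTV gradient recomputed each sub-iteration, so
#' each accepted step moves the image by exactly `eta` in L2 norm.  A
#' vanishing gradient leaves the image unchanged.
#'
#' @inheritParams awtv_gradient
#' @param ng number of sub-iterations (>= 1).
#' @param eta step size in image L2 norm units (> 0).
#' @return updated image array.
#' @export
tv_descent <- function(x, delta, ng, eta, mu = NULL) {
  ng <- as.integer(ng)
  if (is.na(ng) || ng < 1L) stop("'ng' must be >= 1")
  if (!is.finite(eta) || eta <= 0) stop("'eta' must be > 0")
  for (i in seq_len(ng)) {
    s <- awtv_gradient(x, delta, mu)
    ns <- sqrt(sum(s^2))
    if (ns == 0) break
    x <- x - eta * (s / ns)
  }
  x
}
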