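#' Non-negativity projection
#'
#' Elementwise `max(0, x)`: projection onto the convex set of physically
#' admissible (nonnegative-attenuation) images.  Idempotent.
#'
#' @param x image array.
#' @return array of the same shape.
#' @export
nonneg_project <- function(x) {
  x[x < 0] <- 0
  x
}

divide_safe <- function(num, den) {
  out <- num
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out[!ok] <- 0
  out
}

#' One SART sweep over all view angles
#'
#' Sequentially for each angle \eqn{a}:
#' \deqn{x \leftarrow x + \beta V_a^{-1} A_a^T W_a (b_a - A_a x)}
#' with \eqn{W_a} the inverse per-ray intersection-length sums and
#' \eqn{V_a} the per-voxel intersection-length sums, both restricted to
#' that angle's rays (the standard SART normalisation).  Rays or voxels
#' with zero total length contribute zero update.
#'
#' @param x current image estimate (volume-shaped array).
#' @param b measured projections (angles x detector pixels).
#' @param geom a [scan_geometry()].
#' @param beta relaxation factor in (0, 1].
#' @param weights optional per-angle weights from
#'   [sweep_weights()]`(geom)` (computed when omitted).
#' @return updated image array.
#' @export
sart_sweep <- function(x, b, geom, beta = 1, weights = NULL) {
  check_volume(x, geom, "x")
  check_projections(b, geom, "b")
  if (!is.finite(beta) || beta <= 0 || beta > 1)
    stop("'beta' must be in (0, 1]")
  subsets <- as.list(seq_along(geom$angles))
  if (is.null(weights)) weights <- sweep_weights(geom, subsets)
  os_sart_core(x, b, geom, subsets, beta, weights)
}

#' Precompute SART weights for a set of angle subsets
#'
#' One [sart_weights()] per subset (per angle by default), reusable
#' across sweeps and outer iterations.
#'
#' @param geom a [scan_geometry()].
#' @param subsets list of angle-index vectors (default: one per angle).
#' @return list of weight lists, aligned with `subsets`.
#' @export
sweep_weights <- function(geom, subsets = as.list(seq_along(geom$angles))) {
  lapply(subsets, function(s) sart_weights(geom, s))
}

# Shared SART/OS-SART engine: one pass over the given angle subsets,
# each with its own restricted row/column sums.
os_sart_core <- function(x, b, geom, subsets, beta, subw) {
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    r <- b[sub, , drop = FALSE] - forward_project(x, geom, angle_idx = sub)
    wr <- divide_safe(r, subw[[i]]$row_sums)
    corr <- back_project(wr, geom, angle_idx = sub)
    x <- x + beta * divide_safe(corr, subw[[i]]$col_sums)
  }
  x
}

#' Ordered-subsets SART
#'
#' SART-style updates applied to interleaved angle subsets (subset `k`
#' holds angles `k, k + n_subsets, ...`).  With `n_subsets` equal to the
#' number of angles one pass is exactly [sart_sweep()]; with
#' `n_subsets = 1` each pass is a SIRT-like full-data update.
#'
#' @inheritParams sart_sweep
#' @param x0 starting image (default zeros).
#' @param n_subsets number of interleaved angle subsets (1..n_angles).
#' @param n_iter number of passes over all subsets.
#' @return reconstructed image array; deterministic.
#' @export
os_sart <- function(x0 = NULL, b, geom, n_subsets, n_iter = 1, beta = 1) {
  check_projections(b, geom, "b")
  if (is.null(x0)) x0 <- array(0, dim = geom$volume_shape)
  check_volume(x0, geom, "x0")
  n_ang <- length(geom$angles)
  n_subsets <- as.integer(n_subsets)
  if (is.na(n_subsets) || n_subsets < 1L || n_subsets > n_ang)
    stop("'n_subsets' must be between 1 and the number of angles")
  subsets <- lapply(seq_len(n_subsets), function(k) seq(k, n_ang, by = n_subsets))
  subw <- sweep_weights(geom, subsets)
  x <- x0
  for (i in seq_len(n_iter))
    x <- os_sart_core(x, b, geom, subsets, beta, subw)
  x
}

#' Data-driven scale factor for the adaptive-weighted TV norm
#'
#' Runs a fixed short OS-SART reconstruction (defaults: 20 passes,
#' `beta = 1`, `n_subsets = ` half the angles) and returns the 90th
#' percentile of its voxel histogram -- the recommended setting for the
#' AwTV scale factor \eqn{\delta}.  Falls back to a strictly positive
#' floor (1e-8) when the percentile is not positive (e.g. empty data).
#'
#' @inheritParams os_sart
#' @param n_iter,n_subsets,beta OS-SART settings for the probe
#'   reconstruction.
#' @param prob percentile of the voxel histogram (default 0.9).
#' @return strictly positive scalar \eqn{\delta}.
#' @export
estimate_delta <- function(b, geom, n_iter = 20,
                           n_subsets = max(1L, length(geom$angles) %/% 2L),
                           beta = 1, prob = 0.9) {
  x <- os_sart(NULL, b, geom, n_subsets = n_subsets, n_iter = n_iter,
               beta = beta)
  d <- stats::quantile(x, prob, names = FALSE)
  if (!is.finite(d) || d <= 0) 1e-8 else d
}

#' Conjugate gradient least squares (CGLS)
#'
#' Standard CGLS on \eqn{\min_x \|Ax - b\|_2} using the matched
#' projector pair.  By default iteration halts early when the projection
#' residual norm increases (the usual semi-convergence guard for noisy
#' few-view data) or when the normal-equations gradient vanishes.
#'
#' @inheritParams sart_sweep
#' @param x0 starting image (default zeros).
#' @param n_iter maximum iterations (>= 1).
#' @param stop_on_increase halt when `||Ax - b||` grows (default TRUE).
#' @return reconstructed image array with attribute `"iterations"`.
#' @export
cgls <- function(b, geom, n_iter = 50, x0 = NULL, stop_on_increase = TRUE) {
  check_projections(b, geom, "b")
  if (n_iter < 1) stop("'n_iter' must be >= 1")
  if (is.null(x0)) x0 <- array(0, dim = geom$volume_shape)
  check_volume(x0, geom, "x0")
  x <- x0
  r <- b - forward_project(x, geom)
  s <- back_project(r, geom)
  p <- s
  gamma <- sum(s^2)
  gamma0 <- gamma
  res_prev <- sqrt(sum(r^2))
  used <- 0L
  for (k in seq_len(n_iter)) {
    if (gamma <= 1e-28 * max(gamma0, 1)) break
    q <- forward_project(p, geom)
    qq <- sum(q^2)
    if (qq == 0) break
    alpha <- gamma / qq
    x_new <- x + alpha * p
    r <- r - alpha * q
    res <- sqrt(sum(r^2))
    if (stop_on_increase && res > res_prev * (1 + 1e-10)) break
    x <- x_new
    used <- k
    res_prev <- res
    s <- back_project(r, geom)
    gamma_new <- sum(s^2)
    p <- s + (gamma_new / gamma) * p
    gamma <- gamma_new
  }
  attr(x, "iterations") <- used
  x
}
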