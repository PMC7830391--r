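# Image-quality metrics used by the tuner and the evaluation harness.

#' Correlation coefficient between two images
#'
#' Pearson correlation \eqn{CC = \mathrm{Cov}(f, g) / (\sigma_f
#' \sigma_g)} over all voxels, in [-1, 1].  Used as the ant score during
#' hyperparameter tuning.
#'
#' @param recon,reference same-shape numeric arrays; both must have
#'   nonzero variance.
#' @return scalar in [-1, 1].
#' @export
correlation_coefficient <- function(recon, reference) {
  check_same_shape(recon, reference)
  a <- as.numeric(recon); b <- as.numeric(reference)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("correlation coefficient undefined: an image has zero variance")
  stats::cov(a, b) / (stats::sd(a) * stats::sd(b))
}

#' Universal quality index (UQI)
#'
#' \deqn{UQI = \frac{2\,\mathrm{Cov}(\mu, \mu_t)}{\sigma^2 + \sigma_t^2}
#'   \cdot \frac{2\bar\mu\bar\mu_t}{\bar\mu^2 + \bar\mu_t^2}}
#' the product of a covariance/variance (structure + contrast) term and
#' a mean-luminance term; 1 for identical non-constant images, < 1 under
#' any luminance offset or structural mismatch.
#'
#' @inheritParams correlation_coefficient
#' @return scalar (at most 1).
#' @export
uqi <- function(recon, reference) {
  check_same_shape(recon, reference)
  a <- as.numeric(recon); b <- as.numeric(reference)
  v1 <- stats::var(a); v2 <- stats::var(b)
  m1 <- mean(a); m2 <- mean(b)
  if (v1 + v2 == 0 || m1^2 + m2^2 == 0)
    stop("UQI undefined: zero denominator")
  (2 * stats::cov(a, b) / (v1 + v2)) * (2 * m1 * m2 / (m1^2 + m2^2))
}

#' Relative 2-norm error
#'
#' \eqn{e = \|x - x_{ref}\|_2 / \|x_{ref}\|_2}; reported as a percentage
#' in the comparison tables.
#'
#' @inheritParams correlation_coefficient
#' @return nonnegative scalar (fraction, not percent).
#' @export
relative_error <- function(recon, reference) {
  check_same_shape(recon, reference)
  nref <- sqrt(sum(reference^2))
  if (nref == 0) stop("relative error undefined: zero reference")
  sqrt(sum((recon - reference)^2)) / nref
}

#' Root-mean-square error
#'
#' @param a,b same-shape numeric arrays (typically projection data).
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  check_same_shape(a, b)
  sqrt(mean((a - b)^2))
}

#' All image-quality metrics at once
#'
#' @inheritParams correlation_coefficient
#' @return list with `cc`, `uqi`, `relative_error`.
#' @export
metric_report <- function(recon, reference) {
  list(cc = correlation_coefficient(recon, reference),
       uqi = uqi(recon, reference),
       relative_error = relative_error(recon, reference))
}

check_same_shape <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (length(da) != length(db) || !all(da == db))
    stop("images must have identical shapes")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("images must be finite")
  invisible(TRUE)
}
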