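#' Mixed Poisson--Gaussian projection noise model
#'
#' Photon-counting noise for transmission CT: a line integral \eqn{p}
#' corresponds to expected counts \eqn{I = I_0 e^{-p}}; the detector
#' records a Poisson draw of \eqn{I} plus additive Gaussian electronic
#' noise, and the noisy line integral is recovered as
#' \eqn{p' = \log(I_0 / \mathrm{counts})}.  Counts are clipped below at
#' `clip_floor` before the logarithm (photon starvation guard).
#'
#' @param max_photon_count unattenuated photon count \eqn{I_0} (> 0).
#' @param gaussian_mean,gaussian_sd electronic noise mean and standard
#'   deviation, in counts (`gaussian_sd >= 0`).
#' @param seed integer seed making [add_ct_noise()] reproducible.
#' @param clip_floor lower clip for noisy counts (default 1 count).
#' @return object of class `ct_noise_model`.
#' @export
ct_noise_model <- function(max_photon_count = 60000,
                           gaussian_mean = 0,
                           gaussian_sd = 0.5,
                           seed = 1L,
                           clip_floor = 1) {
  if (!is.finite(max_photon_count) || max_photon_count <= 0)
    stop("'max_photon_count' must be > 0")
  if (!is.finite(gaussian_sd) || gaussian_sd < 0)
    stop("'gaussian_sd' must be >= 0")
  structure(list(max_photon_count = as.numeric(max_photon_count),
                 gaussian_mean = as.numeric(gaussian_mean),
                 gaussian_sd = as.numeric(gaussian_sd),
                 seed = as.integer(seed),
                 clip_floor = as.numeric(clip_floor)),
            class = "ct_noise_model")
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Poisson draws that stay exact for small means and switch to the normal
# approximation where rpois would overflow (lambda > 1e7, where the
# relative skew is < 4e-4).
rpois_mixed <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e7
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- stats::rnorm(sum(big), lambda[big], sqrt(lambda[big]))
  out
}

#' Add Poisson--Gaussian noise to projection data
#'
#' @param proj matrix of nonnegative line integrals (angles x detector
#'   pixels).
#' @param noise a [ct_noise_model()]; the default matches the reference
#'   acquisition (\eqn{I_0 = 60000}, Gaussian mean 0, sd 0.5 counts).
#' @return noisy projection matrix of the same shape.  Deterministic for
#'   a fixed `noise$seed`; the caller's RNG state is left untouched.
#' @export
add_ct_noise <- function(proj, noise = ct_noise_model()) {
  stopifnot(inherits(noise, "ct_noise_model"))
  if (!is.matrix(proj) || !all(is.finite(proj)))
    stop("'proj' must be a finite matrix of line integrals")
  if (any(proj < 0))
    stop("line integrals must be nonnegative before noise is applied")
  I0 <- noise$max_photon_count
  with_seed(noise$seed, {
    counts <- rpois_mixed(I0 * exp(-proj)) +
      stats::rnorm(length(proj), noise$gaussian_mean, noise$gaussian_sd)
    counts <- pmax(counts, noise$clip_floor)
    out <- log(I0 / counts)
    dim(out) <- dim(proj)
    out
  })
}
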