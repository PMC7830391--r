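#' Hyperparameters for the AwPCSD algorithm
#'
#' The five tunable hyperparameters of adaptive-weighted
#' projection-controlled steepest descent, plus iteration limits and the
#' two stopping thresholds.
#'
#' @param epsilon data-inconsistency tolerance \eqn{\varepsilon} (>= 0):
#'   the SART phase runs while the squared projection residual exceeds
#'   it, and the convergence stopping rule requires the (unsquared)
#'   residual `dd <= epsilon`.
#' @param ng TV sub-iterations per outer iteration (>= 1).
#' @param beta initial SART relaxation \eqn{\beta \in (0, 1]}.
#' @param beta_red geometric reduction factor of `beta` per outer
#'   iteration, in (0, 1); values just above 0.98 are recommended.
#' @param delta adaptive-weight scale factor (> 0); see
#'   [estimate_delta()].
#' @param k TV step-size scale constant (default 1).
#' @param max_iter outer iteration cap (>= 1).
#' @param beta_floor stop once `beta` decays below this (default 0.005).
#' @param c_threshold cosine stopping threshold (default -0.99): stop
#'   when the data-fidelity and TV update steps point in nearly opposite
#'   directions and the residual is within `epsilon`.
#' @param mu TV gradient smoothing constant passed to [awtv_gradient()]
#'   (NULL for its image-scaled default).
#' @return object of class `awpcsd_params`.
#' @export
awpcsd_params <- function(epsilon, ng, delta,
                          beta = 1, beta_red = 0.99, k = 1,
                          max_iter = 50, beta_floor = 0.005,
                          c_threshold = -0.99, mu = NULL) {
  if (!is.finite(epsilon) || epsilon < 0) stop("'epsilon' must be >= 0")
  ng <- as.integer(ng)
  if (is.na(ng) || ng < 1L) stop("'ng' must be >= 1")
  if (!is.finite(delta) || delta <= 0) stop("'delta' must be > 0")
  if (!is.finite(beta) || beta <= 0 || beta > 1)
    stop("'beta' must be in (0, 1]")
  if (!is.finite(beta_red) || beta_red <= 0 || beta_red >= 1)
    stop("'beta_red' must be in (0, 1)")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("'max_iter' must be >= 1")
  structure(list(epsilon = epsilon, ng = ng, delta = delta,
                 beta = beta, beta_red = beta_red, k = k,
                 max_iter = max_iter, beta_floor = beta_floor,
                 c_threshold = c_threshold, mu = mu),
            class = "awpcsd_params")
}

#' Adaptive-weighted projection-controlled steepest descent (AwPCSD)
#'
#' Total-variation-regularised iterative reconstruction for few-view CT.
#' Each outer iteration `w`:
#' \enumerate{
#'   \item records the projection residual `dd = ||Ax - b||_2`;
#'   \item if `dd^2 > epsilon`, applies one full [sart_sweep()] with the
#'     current relaxation `beta` (data-fidelity phase);
#'   \item projects onto nonnegative images, `x <- max(0, x)`;
#'   \item decays the relaxation, `beta <- beta * beta_red`;
#'   \item sets the TV step control `eta = k * dd(w) / dd(1)` (`eta = 1`
#'     on the first iteration; clamped to (0, 10]) and runs
#'     [tv_descent()] for `ng` sub-iterations with step size
#'     `eta * dp`, where `dp` is the image-space L2 norm of this
#'     iteration's data-update step.  Scaling the projection-controlled
#'     `eta` by the data-step norm keeps the TV phase commensurate with
#'     the data phase at any image scale; when the SART phase is gated
#'     off (`dd^2 <= epsilon`) the data step is zero and the iteration
#'     leaves the image unchanged.
#' }
#' Stopping: `beta < beta_floor`, or `c < c_threshold` together with
#' `dd <= epsilon` where `c` is the cosine of the angle between the
#' data-update step and the TV-update step of the iteration (0 when
#' either step vanishes), or the outer iteration cap.
#'
#' Passing `n_outer` runs at most that many further iterations and
#' returns a resumable result: feeding its `$state` back via `state`
#' continues the run exactly as if it had never been interrupted (the
#' warm-start contract used by the ant-colony tuner, which also swaps
#' `epsilon`/`ng` between resumptions).
#'
#' @param x0 starting image (default zeros; ignored when `state` given).
#' @param b measured projections (angles x detector pixels).
#' @param geom a [scan_geometry()].
#' @param params an [awpcsd_params()].
#' @param n_outer optional cap on iterations for this call.
#' @param state a `$state` from a previous call to resume.
#' @param weights optional per-angle weights from [sweep_weights()].
#' @return object of class `awpcsd_result`: `image`, `trace` (data frame
#'   with columns iter, dd, awtv, beta, eta, dtv, c), `stop_reason` (one of
#'   `"max_iter"`, `"beta_floor"`, `"converged_c_dd"`, or `NA` if the
#'   run is merely paused), and `state` for resumption.
#' @export
awpcsd <- function(x0 = NULL, b, geom, params, n_outer = NULL,
                   state = NULL, weights = NULL) {
  stopifnot(inherits(geom, "scan_geometry"), inherits(params, "awpcsd_params"))
  check_projections(b, geom, "b")
  subsets <- as.list(seq_along(geom$angles))
  if (is.null(weights)) weights <- sweep_weights(geom, subsets)

  if (is.null(state)) {
    if (is.null(x0)) x0 <- array(0, dim = geom$volume_shape)
    check_volume(x0, geom, "x0")
    state <- list(x = x0, beta = params$beta, dd_ref = NA_real_,
                  iter = 0L, trace = NULL, stop_reason = NA_character_)
  }
  if (!is.na(state$stop_reason)) {   # already terminated
    return(structure(list(image = state$x, trace = state$trace,
                          stop_reason = state$stop_reason, state = state),
                     class = "awpcsd_result"))
  }

  x <- state$x
  done_this_call <- 0L
  repeat {
    if (!is.null(n_outer) && done_this_call >= n_outer) break
    w <- state$iter + 1L
    x_start <- x
    dd <- sqrt(sum((forward_project(x, geom) - b)^2))
    if (is.na(state$dd_ref)) state$dd_ref <- dd

    beta_used <- state$beta
    if (dd^2 > params$epsilon)
      x <- os_sart_core(x, b, geom, subsets, beta_used, weights)
    x <- nonneg_project(x)
    x_pocs <- x
    state$beta <- state$beta * params$beta_red

    dp <- sqrt(sum((x_pocs - x_start)^2))
    eta <- if (w == 1L) 1
           else params$k * dd / state$dd_ref
    eta <- min(max(eta, 1e-12), 10)
    dtv <- eta * dp
    if (dtv > 0)
      x <- tv_descent(x_pocs, params$delta, params$ng, dtv, params$mu)

    d_data <- x_pocs - x_start
    d_tv <- x - x_pocs
    n1 <- sqrt(sum(d_data^2)); n2 <- sqrt(sum(d_tv^2))
    cc <- if (n1 == 0 || n2 == 0) 0 else sum(d_data * d_tv) / (n1 * n2)

    state$trace <- rbind(state$trace,
      data.frame(iter = w, dd = dd, awtv = awtv_norm(x, params$delta),
                 beta = beta_used, eta = eta, dtv = dtv, c = cc))
    state$iter <- w
    done_this_call <- done_this_call + 1L

    if (state$beta < params$beta_floor) {
      state$stop_reason <- "beta_floor"
    } else if (cc < params$c_threshold && dd <= params$epsilon) {
      state$stop_reason <- "converged_c_dd"
    } else if (w >= params$max_iter) {
      state$stop_reason <- "max_iter"
    }
    if (!is.na(state$stop_reason)) break
  }
  state$x <- x
  structure(list(image = x, trace = state$trace,
                 stop_reason = state$stop_reason, state = state),
            class = "awpcsd_result")
}

#' @export
print.awpcsd_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("<awpcsd_result> %d outer iteration%s, stop: %s\n",
              n, if (n == 1) "" else "s",
              if (is.na(x$stop_reason)) "paused" else x$stop_reason))
  if (n > 0)
    cat(sprintf("  final dd = %.6g, AwTV = %.6g, beta = %.4g\n",
                x$trace$dd[n], x$trace$awtv[n], x$trace$beta[n]))
  invisible(x)
}
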