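#' Leave-one-angle-out split of projection data
#'
#' Removes one view angle from the projections: the remaining angles
#' form the training set, the removed angle the held-out test set, each
#' with a consistently restricted geometry.
#'
#' @param b projections (angles x detector pixels).
#' @param geom a [scan_geometry()] with at least 2 angles.
#' @param angle_index 1-based index of the held-out angle.
#' @return list with `train` and `test`, each a list of `b` and `geom`.
#' @export
loo_split <- function(b, geom, angle_index) {
  stopifnot(inherits(geom, "scan_geometry"))
  check_projections(b, geom, "b")
  n <- length(geom$angles)
  if (n < 2L) stop("leave-one-out needs at least 2 angles")
  angle_index <- as.integer(angle_index)
  if (is.na(angle_index) || angle_index < 1L || angle_index > n)
    stop("'angle_index' out of range")
  keep <- setdiff(seq_len(n), angle_index)
  list(train = list(b = b[keep, , drop = FALSE],
                    geom = subset_angles(geom, keep)),
       test = list(b = b[angle_index, , drop = FALSE],
                   geom = subset_angles(geom, angle_index)))
}

#' Cross-validation score of one hyperparameter configuration
#'
#' For each trial angle: reconstruct with AwPCSD from all other angles,
#' forward-project the result onto the held-out angle, and measure the
#' RMSE against the held-out projection.  Returns the mean over trials.
#'
#' @param config list with `epsilon` and `ng`.
#' @param b,geom projections and geometry.
#' @param space a [search_space()] supplying the pinned hyperparameters.
#' @param trial_angles 1-based indices of held-out angles.
#' @param max_iter AwPCSD outer iteration cap per trial (default 50).
#' @return list: `mean_rmse` and per-trial `rmse` vector.
#' @export
cv_score_config <- function(config, b, geom, space, trial_angles,
                            max_iter = 50) {
  trial_angles <- as.integer(trial_angles)
  if (length(trial_angles) < 1L) stop("'trial_angles' must be non-empty")
  params <- awpcsd_params(
    epsilon = config$epsilon, ng = config$ng, delta = space$fixed$delta,
    beta = space$fixed$beta, beta_red = space$fixed$beta_red,
    k = space$fixed$k, max_iter = max_iter)
  per_trial <- vapply(trial_angles, function(a) {
    sp <- loo_split(b, geom, a)
    rec <- tryCatch(
      awpcsd(b = sp$train$b, geom = sp$train$geom, params = params),
      error = function(e)
        stop(sprintf("trial angle %d: %s", a, conditionMessage(e)),
             call. = FALSE))
    sim <- forward_project(rec$image, sp$test$geom)
    rmse(sim, sp$test$b)
  }, numeric(1))
  list(mean_rmse = mean(per_trial), rmse = per_trial)
}

#' Cross-validation hyperparameter selection
#'
#' Evaluates every configuration of the search space by
#' leave-one-angle-out cross-validation over a shared set of trial
#' angles and picks the configuration with the lowest mean held-out
#' RMSE (ties broken by lowest candidate indices).  Deterministic.
#'
#' Full leave-one-out over all angles is the reference procedure but is
#' expensive; `trial_stride` keeps every `stride`-th angle as a trial
#' (1 = full leave-one-out), and is recorded in the result.
#'
#' @inheritParams cv_score_config
#' @param trial_angles explicit trial angle indices, or `NULL` to derive
#'   them from `trial_stride`.
#' @param trial_stride stride through the angle list when
#'   `trial_angles` is `NULL` (default 1: all angles).
#' @return object of class `cv_tune_result`: `best_config`,
#'   `per_config_mean_rmse` (array over the grid), `rmse_table`
#'   (configurations x trials), `trial_angles`, `trial_stride`.
#' @export
cv_tune <- function(b, geom, space, trial_angles = NULL, trial_stride = 1L,
                    max_iter = 50) {
  stopifnot(inherits(space, "search_space"))
  if (is.null(trial_angles))
    trial_angles <- seq(1L, length(geom$angles), by = as.integer(trial_stride))
  trial_angles <- as.integer(trial_angles)
  dims <- vapply(space$dimensions, length, integer(1))
  grid <- expand.grid(lapply(dims, seq_len), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(space$dimensions)
  mean_rmse <- array(NA_real_, dim = dims,
                     dimnames = lapply(space$dimensions, as.character))
  tab <- matrix(NA_real_, nrow = nrow(grid), ncol = length(trial_angles),
                dimnames = list(NULL, paste0("angle", trial_angles)))
  for (r in seq_len(nrow(grid))) {
    idx <- vapply(names(space$dimensions),
                  function(nm) as.integer(grid[[nm]][r]), integer(1))
    config <- lapply(stats::setNames(names(space$dimensions),
                                     names(space$dimensions)),
                     function(nm) space$dimensions[[nm]][idx[[nm]]])
    sc <- cv_score_config(config, b, geom, space, trial_angles, max_iter)
    tab[r, ] <- sc$rmse
    mean_rmse[matrix(idx, 1L)] <- sc$mean_rmse
  }
  bi <- argbest_config(mean_rmse, maximize = FALSE)
  names(bi) <- names(space$dimensions)
  best_values <- lapply(stats::setNames(names(space$dimensions),
                                        names(space$dimensions)),
                        function(nm) space$dimensions[[nm]][bi[[nm]]])
  structure(list(
    best_config = list(idx = bi, values = best_values, fixed = space$fixed),
    per_config_mean_rmse = mean_rmse,
    rmse_table = tab,
    config_grid = grid,
    trial_angles = trial_angles,
    trial_stride = if (is.null(trial_stride)) NA_integer_
                   else as.integer(trial_stride)),
    class = "cv_tune_result")
}

#' @export
print.cv_tune_result <- function(x, ...) {
  cat("<cv_tune_result>\n")
  vals <- vapply(x$best_config$values, function(v) format(v), character(1))
  cat(sprintf("  best config : %s (mean held-out RMSE %.6g)\n",
              paste(names(vals), vals, sep = " = ", collapse = ", "),
              min(x$per_config_mean_rmse)))
  cat(sprintf("  trials      : %d held-out angles\n", length(x$trial_angles)))
  invisible(x)
}
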