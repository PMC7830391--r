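#' Discrete hyperparameter search space
#'
#' An ordered set of candidate values per searched hyperparameter
#' (`epsilon`, `ng`) plus the pinned hyperparameters (`beta`,
#' `beta_red`, `delta`).  Total configurations = product of the list
#' lengths.
#'
#' @param dimensions named list of candidate-value vectors, in search
#'   order; each non-empty with distinct values.
#' @param fixed named list of pinned hyperparameters; must contain
#'   `delta` (and may contain `beta`, `beta_red`, `k`).
#' @return object of class `search_space`.
#' @export
search_space <- function(dimensions, fixed) {
  if (!is.list(dimensions) || length(dimensions) < 1L ||
      is.null(names(dimensions)) || any(names(dimensions) == ""))
    stop("'dimensions' must be a named list of candidate vectors")
  for (nm in names(dimensions)) {
    v <- dimensions[[nm]]
    if (length(v) < 1L || anyDuplicated(v) || anyNA(v))
      stop(sprintf("dimension '%s' must be non-empty with distinct values", nm))
  }
  if (is.null(fixed$delta)) stop("'fixed' must supply delta")
  fixed <- utils::modifyList(list(beta = 1, beta_red = 0.99, k = 1), fixed)
  structure(list(dimensions = dimensions, fixed = fixed),
            class = "search_space")
}

#' The reference hyperparameter grid
#'
#' The standard 150-configuration grid searched by the tuner: 10
#' candidate values for the data-inconsistency tolerance `epsilon`
#' (0 to 5e5, wide to cover measurement and modelling error) and 15 for
#' the TV sub-iteration count `ng` (2 to 30), with `beta = 1`,
#' `beta_red = 0.99` pinned and `delta` supplied by the caller (usually
#' from [estimate_delta()]).
#'
#' @param delta pinned AwTV scale factor.
#' @return a [search_space()] with `10 * 15 = 150` configurations.
#' @export
default_search_space <- function(delta) {
  search_space(
    dimensions = list(
      epsilon = c(0, 50, 70, 100, 200, 500, 2e3, 1e4, 1e5, 5e5),
      ng = seq(2L, 30L, by = 2L)),
    fixed = list(delta = delta))
}

n_configurations <- function(space) {
  prod(vapply(space$dimensions, length, integer(1)))
}

#' A search grid calibrated to the data's residual scale
#'
#' The reference grid's `epsilon` candidates were chosen "very wide" for
#' the training data they were used with; `epsilon` bounds a squared
#' projection residual, so its useful range scales with
#' \eqn{\|b\|_2^2}.  This builder keeps the reference grid's shape (10
#' `epsilon` values including 0, the same 15 `ng` values) but spans
#' `epsilon` logarithmically from `||b||^2 / 1e5` up to `||b||^2`, so
#' the SART gate-off threshold sweeps the whole convergence trajectory
#' whatever the problem scale.
#'
#' @param b projection data (angles x detector pixels).
#' @param geom the matching [scan_geometry()] (unused beyond validation).
#' @param delta pinned AwTV scale factor.
#' @param n_epsilon number of `epsilon` candidates (>= 2; first is 0).
#' @param ng candidate TV sub-iteration counts.
#' @return a [search_space()].
#' @export
scaled_search_space <- function(b, geom, delta, n_epsilon = 10,
                                ng = seq(2L, 30L, by = 2L)) {
  check_projections(b, geom, "b")
  eps_max <- sum(b^2)
  eps <- c(0, 10^seq(log10(eps_max) - 5, log10(eps_max),
                     length.out = n_epsilon - 1))
  search_space(dimensions = list(epsilon = eps, ng = ng),
               fixed = list(delta = delta))
}

#' Ant colony settings
#'
#' Defaults are the reference training setup: 50 ants per generation,
#' at most 10 generations per iteration, at most 50 iterations,
#' evaporation rate 1.
#'
#' @param n_ants ants per generation (>= 1).
#' @param max_generations generation budget per iteration (>= 1).
#' @param max_iterations iteration cap (>= 1).
#' @param evaporation pheromone evaporation rate \eqn{\sigma} in [0, 1].
#' @param seed integer seed; the whole tuning run is reproducible.
#' @param gen_reset whether the generation counter resets when a new
#'   iteration starts (default TRUE: the generation budget is
#'   per-iteration).
#' @return object of class `colony_config`.
#' @export
colony_config <- function(n_ants = 50, max_generations = 10,
                          max_iterations = 50, evaporation = 1,
                          seed = 1L, gen_reset = TRUE) {
  n_ants <- as.integer(n_ants)
  max_generations <- as.integer(max_generations)
  max_iterations <- as.integer(max_iterations)
  if (any(is.na(c(n_ants, max_generations, max_iterations))) ||
      n_ants < 1L || max_generations < 1L || max_iterations < 1L)
    stop("counts must be >= 1")
  if (!is.finite(evaporation) || evaporation < 0 || evaporation > 1)
    stop("'evaporation' must be in [0, 1]")
  structure(list(n_ants = n_ants, max_generations = max_generations,
                 max_iterations = max_iterations, evaporation = evaporation,
                 seed = as.integer(seed), gen_reset = isTRUE(gen_reset)),
            class = "colony_config")
}

#' Selection probabilities from pheromones
#'
#' \eqn{P_i = \tau_i / \sum_q \tau_q}.
#'
#' @param tau nonnegative pheromone vector with positive sum.
#' @return probability vector summing to 1.
#' @export
choice_probabilities <- function(tau) {
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("pheromones must be finite and >= 0")
  s <- sum(tau)
  if (s <= 0) stop("degenerate pheromone state: all pheromones are zero")
  tau / s
}

#' Initial pheromone state for a search space
#'
#' All pheromones start at 1 so every candidate is equally likely for
#' the first generation of ants.
#'
#' @param space a [search_space()].
#' @param evaporation evaporation rate \eqn{\sigma} in [0, 1].
#' @return object of class `pheromone_state`: per-dimension pheromone
#'   vectors `tau`, generation counter `generation`, `evaporation`.
#' @export
pheromone_state <- function(space, evaporation = 1) {
  stopifnot(inherits(space, "search_space"))
  tau <- lapply(space$dimensions, function(v) rep(1, length(v)))
  structure(list(tau = tau, generation = 0L, evaporation = evaporation),
            class = "pheromone_state")
}

#' Sample one hyperparameter configuration
#'
#' One independent categorical draw per dimension with probabilities
#' from [choice_probabilities()]; uses (and advances) R's global RNG.
#'
#' @param pheromones a [pheromone_state()].
#' @param space the matching [search_space()].
#' @return list with `idx` (named integer candidate indices) and
#'   `values` (named list of the chosen values).
#' @export
sample_config <- function(pheromones, space) {
  idx <- vapply(names(space$dimensions), function(nm) {
    p <- choice_probabilities(pheromones$tau[[nm]])
    sample.int(length(p), 1L, prob = p)
  }, integer(1))
  list(idx = idx,
       values = lapply(stats::setNames(names(space$dimensions),
                                       names(space$dimensions)),
                       function(nm) space$dimensions[[nm]][idx[[nm]]]))
}

#' Evaluate one ant
#'
#' Runs a single AwPCSD outer iteration from the previous-iteration-best
#' image (carried in `state`) with the ant's sampled `epsilon`/`ng` and
#' the pinned hyperparameters, and scores the result by correlation
#' coefficient against the reference image.  A failed reconstruction is
#' scored -1.
#'
#' @param config a configuration from [sample_config()].
#' @param state resumable AwPCSD state holding the previous-iteration
#'   best image, current relaxation and step-size reference (see
#'   [awpcsd()]); `NULL` starts from zeros.
#' @param b,geom projections and geometry.
#' @param reference reference image for scoring.
#' @param space the [search_space()] (for the pinned hyperparameters).
#' @param weights optional per-angle weights from [sweep_weights()].
#' @return list: `image`, `score`, `state` (for warm-starting the next
#'   iteration), `stop_reason`, `ok`.
#' @export
score_ant <- function(config, state, b, geom, reference, space,
                      weights = NULL) {
  params <- awpcsd_params(
    epsilon = config$values$epsilon, ng = config$values$ng,
    delta = space$fixed$delta, beta = space$fixed$beta,
    beta_red = space$fixed$beta_red, k = space$fixed$k,
    max_iter = .Machine$integer.max)
  res <- tryCatch(
    awpcsd(b = b, geom = geom, params = params, n_outer = 1L,
           state = state, weights = weights),
    error = function(e) e)
  if (inherits(res, "error"))
    return(list(image = NULL, score = -1, state = state,
                stop_reason = NA_character_, ok = FALSE,
                message = conditionMessage(res)))
  score <- tryCatch(correlation_coefficient(res$image, reference),
                    error = function(e) -1)
  list(image = res$image, score = score, state = res$state,
       stop_reason = res$stop_reason, ok = TRUE)
}

#' Pheromone update from one generation of ants
#'
#' For every candidate value `i` chosen by at least one ant:
#' \eqn{\tau_i \leftarrow (1 - \sigma)\tau_i + \bar s_i} where
#' \eqn{\bar s_i} is the mean score of the ants that chose `i`; values
#' no ant chose carry no new evidence and keep their pheromone.  Each
#' dimension is then normalised by its maximum so pheromones lie in
#' [0, 1] with max 1.  Negative pheromones (possible only with negative
#' scores) are clamped at 0; if a whole dimension collapses to 0 it is
#' reset to uniform.
#'
#' @param pheromones a [pheromone_state()].
#' @param scores list of per-ant records, each with `config` (from
#'   [sample_config()]) and `score`.
#' @return updated `pheromone_state` (generation counter advanced).
#' @export
update_pheromones <- function(pheromones, scores) {
  stopifnot(inherits(pheromones, "pheromone_state"))
  if (length(scores) < 1L) stop("'scores' must be non-empty")
  sigma <- pheromones$evaporation
  for (nm in names(pheromones$tau)) {
    tau <- pheromones$tau[[nm]]
    chosen <- vapply(scores, function(s) s$config$idx[[nm]], integer(1))
    sc <- vapply(scores, function(s) s$score, numeric(1))
    for (i in unique(chosen))
      tau[i] <- (1 - sigma) * tau[i] + mean(sc[chosen == i])
    tau <- pmax(tau, 0)
    mx <- max(tau)
    pheromones$tau[[nm]] <- if (mx > 0) tau / mx else rep(1, length(tau))
  }
  pheromones$generation <- pheromones$generation + 1L
  pheromones
}

# Lexicographically first index combination among tied maxima.
argbest_config <- function(values_array, maximize = TRUE) {
  target <- if (maximize) max(values_array) else min(values_array)
  hits <- which(values_array == target, arr.ind = TRUE)
  if (is.vector(hits)) hits <- matrix(hits, ncol = 1L)
  hits <- matrix(as.integer(hits), nrow = nrow(hits))
  ord <- do.call(order, as.data.frame(hits))
  hits[ord[1L], ]
}

#' Ant-colony hyperparameter tuning for AwPCSD
#'
#' Searches the discrete (`epsilon`, `ng`) grid by swarming ants through
#' one-iteration AwPCSD reconstructions scored against a reference
#' image.  Each generation, `n_ants` ants sample a configuration from
#' the pheromone probabilities, run one outer iteration warm-started at
#' the previous-iteration-best image, and deposit their correlation
#' score; pheromones evaporate and are max-normalised.  When a
#' generation improves on the previous one the search advances an
#' iteration (the winning image becomes the new warm-start base and the
#' relaxation decays), otherwise another generation is launched;
#' exhausting the per-iteration generation budget also advances an
#' iteration, so the search runs until the iteration cap (or until an
#' ant's reconstruction meets the solver's own stopping criteria).
#' Every ant's score also accumulates into its
#' configuration's cell; the final answer is the configuration with the
#' highest accumulated score.
#'
#' @param b projections (angles x detector pixels).
#' @param geom a [scan_geometry()].
#' @param reference reference image for scoring (ground truth phantom,
#'   or a full-data reconstruction in applied settings).
#' @param space a [search_space()].
#' @param colony a [colony_config()].
#' @param final_recon run a full AwPCSD reconstruction with the winning
#'   configuration for `$best_image` (default TRUE).
#' @param score_fn scoring hook `(config, state) -> list(image, score,
#'   state, stop_reason, ok)`; defaults to [score_ant()].  Used by tests
#'   to substitute a deterministic objective.
#' @return object of class `aco_tune_result`: `best_config`,
#'   `accumulated_scores` (per-configuration matrix/array),
#'   `best_image`, `prev_iter_best`, `history` (per-generation records),
#'   `pheromones`, `stop_reason`, `n_iterations`, `n_generations`.
#' @export
aco_tune <- function(b, geom, reference, space, colony = colony_config(),
                     final_recon = TRUE, score_fn = NULL) {
  stopifnot(inherits(space, "search_space"), inherits(colony, "colony_config"))
  weights <- if (is.null(score_fn)) sweep_weights(geom) else NULL
  if (is.null(score_fn))
    score_fn <- function(config, state)
      score_ant(config, state, b, geom, reference, space, weights)

  dims <- vapply(space$dimensions, length, integer(1))
  acc <- array(0, dim = dims,
               dimnames = lapply(space$dimensions, as.character))
  ph <- pheromone_state(space, colony$evaporation)
  master <- NULL          # awpcsd state; NULL until the first winner
  prev_gen_best <- -Inf
  history <- list()
  w <- 1L; g <- 1L
  stop_reason <- NA_character_

  with_seed(colony$seed, {
    repeat {
      ants <- vector("list", colony$n_ants)
      for (a in seq_len(colony$n_ants)) {
        config <- sample_config(ph, space)
        r <- score_fn(config, master)
        ants[[a]] <- list(config = config, score = r$score,
                          image = r$image, state = r$state,
                          stop_reason = r$stop_reason, ok = r$ok)
        acc[matrix(config$idx, 1L)] <- acc[matrix(config$idx, 1L)] + r$score
      }
      sc <- vapply(ants, `[[`, numeric(1), "score")
      idxm <- do.call(rbind, lapply(ants, function(x) x$config$idx))
      ord <- do.call(order, c(list(-sc), as.data.frame(idxm)))
      best_ant <- ants[[ord[1L]]]
      cur_best <- best_ant$score

      ph <- update_pheromones(ph, lapply(ants, `[`, c("config", "score")))
      history[[length(history) + 1L]] <- list(
        iteration = w, generation = g,
        configs = idxm, scores = sc,
        gen_best_score = cur_best, gen_best_config = best_ant$config,
        tau = ph$tau)

      converged <- any(vapply(ants, function(x)
        isTRUE(x$stop_reason %in% c("converged_c_dd", "beta_floor")),
        logical(1)))
      if (converged) { stop_reason <- "recon_converged"; break }

      prev_gen_best_before <- prev_gen_best
      prev_gen_best <- cur_best
      advance <- (cur_best > prev_gen_best_before ||
                    g >= colony$max_generations) &&
        w < colony$max_iterations
      if (advance) {
        # improvement -- or generation budget exhausted: the search
        # advances an iteration, re-basing on the current best
        master <- best_ant$state
        w <- w + 1L
        g <- if (colony$gen_reset) 1L else g + 1L
        if (!colony$gen_reset && g > colony$max_generations) {
          stop_reason <- "max_generations"; break
        }
      } else {
        # at the iteration cap the colony keeps sampling generations at
        # the fixed base until the generation budget is exhausted
        g <- g + 1L
        if (g > colony$max_generations) {
          stop_reason <- if (w >= colony$max_iterations) "max_iterations"
                         else "max_generations"
          break
        }
      }
    }
  })

  bi <- argbest_config(acc)
  names(bi) <- names(space$dimensions)
  best_values <- lapply(stats::setNames(names(space$dimensions),
                                        names(space$dimensions)),
                        function(nm) space$dimensions[[nm]][bi[[nm]]])
  best_image <- NULL
  if (final_recon) {
    params <- awpcsd_params(
      epsilon = best_values$epsilon, ng = best_values$ng,
      delta = space$fixed$delta, beta = space$fixed$beta,
      beta_red = space$fixed$beta_red, k = space$fixed$k,
      max_iter = colony$max_iterations)
    best_image <- awpcsd(b = b, geom = geom, params = params,
                         weights = weights)$image
  }

  structure(list(
    best_config = list(idx = bi, values = best_values, fixed = space$fixed),
    accumulated_scores = acc,
    best_image = best_image,
    prev_iter_best = if (is.null(master)) NULL else master$x,
    history = history,
    pheromones = ph,
    stop_reason = stop_reason,
    n_iterations = w,
    n_generations = length(history)),
    class = "aco_tune_result")
}

#' @export
print.aco_tune_result <- function(x, ...) {
  cat("<aco_tune_result>\n")
  vals <- vapply(x$best_config$values, function(v) format(v), character(1))
  cat(sprintf("  best config : %s\n",
              paste(names(vals), vals, sep = " = ", collapse = ", ")))
  cat(sprintf("  search      : %d iterations, %d generations, stop: %s\n",
              x$n_iterations, x$n_generations, x$stop_reason))
  invisible(x)
}
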