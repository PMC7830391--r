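#' Desk-scale experiment plan
#'
#' Bundles everything needed to compare hyperparameter-selection methods
#' on the synthetic thorax-like phantom: geometry, noise cases, methods,
#' the search grid, the colony and seeds.  Defaults reproduce the
#' reference comparison pattern at desk scale: a 64x64 fan-beam phantom,
#' 50 views over 360 degrees, default noise (photon count 60000, Gaussian
#' sd 0.5) plus three harsher noise cases, and four methods -- ACO-tuned
#' AwPCSD, cross-validated AwPCSD, AwPCSD with the arbitrary setting
#' (epsilon 700, ng 100) and CGLS.
#'
#' @param grid_shape phantom/reconstruction grid (default `c(64, 64)`).
#' @param voxel_size voxel size in mm (default 5: a ~320 mm thorax field
#'   of view at 64 voxels).
#' @param beam_mode acquisition mode (default `"fan2d"`).
#' @param span_degrees,n_views,start_angle view sampling (default 50
#'   views over 360 degrees).
#' @param phantom_variant `"training"`, `"male"` or `"female"`.
#' @param noise_cases named list of [ct_noise_model()] argument lists;
#'   the default holds the reference four: default / noise1 / noise2 /
#'   noise3 with photon counts 60000 / 30000 / 20000 / 10000 and
#'   Gaussian sd 0.5 / 1 / 3 / 5.
#' @param methods subset of `c("tuned", "cv", "arbitrary", "cgls")`.
#'   Cross-validation evaluates every grid configuration with a full
#'   reconstruction per trial angle and takes hours at 64^2 even
#'   strided, so it is not in the default method list.
#' @param arbitrary the arbitrary hyperparameter setting (epsilon 700,
#'   ng 100).
#' @param colony a [colony_config()]; the default here is desk-scale
#'   (50 ants, a 3-iteration horizon with a 12-generation terminal
#'   sampling phase) rather than the full reference colony, to keep
#'   runs in minutes -- see the methods vignette for why the iteration
#'   budget tracks the convergence horizon.
#' @param space optional [search_space()]; `NULL` builds
#'   [default_search_space()] with delta from [estimate_delta()] on the
#'   default-noise projections.
#' @param cv_trial_stride stride of cross-validation trial angles
#'   (default 10: 5 of 50 angles).
#' @param max_iter reconstruction iteration cap for every method.
#' @param seed base seed; noise case `i` uses `seed + i - 1`, the
#'   colony uses `seed`.
#' @return object of class `experiment_plan`.
#' @export
experiment_plan <- function(grid_shape = c(64, 64), voxel_size = 5,
                            beam_mode = "fan2d",
                            span_degrees = 360, n_views = 50,
                            start_angle = 0,
                            phantom_variant = "training",
                            noise_cases = NULL,
                            methods = c("tuned", "arbitrary", "cgls"),
                            arbitrary = list(epsilon = 700, ng = 100),
                            colony = colony_config(n_ants = 50,
                                                   max_generations = 12,
                                                   max_iterations = 3),
                            space = NULL,
                            cv_trial_stride = 10L,
                            max_iter = 50L,
                            seed = 1L) {
  if (is.null(noise_cases))
    noise_cases <- list(
      default = list(max_photon_count = 60000, gaussian_sd = 0.5),
      noise1  = list(max_photon_count = 30000, gaussian_sd = 1),
      noise2  = list(max_photon_count = 20000, gaussian_sd = 3),
      noise3  = list(max_photon_count = 10000, gaussian_sd = 5))
  methods <- match.arg(methods, c("tuned", "cv", "arbitrary", "cgls"),
                       several.ok = TRUE)
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 beam_mode = beam_mode, span_degrees = span_degrees,
                 n_views = n_views, start_angle = start_angle,
                 phantom_variant = phantom_variant,
                 noise_cases = noise_cases, methods = methods,
                 arbitrary = arbitrary, colony = colony, space = space,
                 cv_trial_stride = as.integer(cv_trial_stride),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

# Detector mirrors the reference proportions: as many detector pixels as
# image columns, pitch chosen so the detector covers the field of view
# at the detector plane (few-view and slightly underdetermined).
plan_geometry <- function(plan) {
  mag <- if (plan$beam_mode == "parallel2d") 1 else 2
  scan_geometry(plan$beam_mode,
                angles = make_angles(plan$span_degrees, plan$n_views,
                                     plan$start_angle),
                volume_shape = plan$grid_shape,
                voxel_size = plan$voxel_size,
                detector_pixel_counts = plan$grid_shape[1],
                detector_pixel_pitch = plan$voxel_size * mag)
}

plan_noisy_projections <- function(plan, truth, geom) {
  clean <- forward_project(truth, geom)
  out <- vector("list", length(plan$noise_cases))
  names(out) <- names(plan$noise_cases)
  for (i in seq_along(plan$noise_cases)) {
    args <- plan$noise_cases[[i]]
    args$seed <- plan$seed + i - 1L
    out[[i]] <- add_ct_noise(clean, do.call(ct_noise_model, args))
  }
  out
}

awpcsd_config_recon <- function(config, b, geom, fixed, max_iter) {
  params <- awpcsd_params(
    epsilon = config$epsilon, ng = config$ng, delta = fixed$delta,
    beta = fixed$beta, beta_red = fixed$beta_red, k = fixed$k,
    max_iter = max_iter)
  awpcsd(b = b, geom = geom, params = params)$image
}

#' Run the method-comparison experiment
#'
#' Selects hyperparameters on the default-noise projections (ACO and
#' cross-validation as requested), then reconstructs every noise case
#' with every method and scores each result against the ground-truth
#' phantom.  Method failures are recorded per row and the run continues.
#'
#' @param plan an [experiment_plan()].
#' @return object of class `comparison_result`: `table` (data frame
#'   with case, method, epsilon, ng, relative_error_pct, uqi, cc,
#'   status), `images` (per case, per method), `profiles` (centre-row
#'   profiles incl. the truth), `diff_images` (reconstruction minus
#'   truth), `truth`, `configs`, `plan`.
#' @export
run_comparison <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  geom <- plan_geometry(plan)
  truth <- render_phantom(thorax_phantom_spec(plan$grid_shape,
                                              plan$phantom_variant))
  projs <- plan_noisy_projections(plan, truth, geom)
  b0 <- projs[[1L]]

  space <- plan$space
  if (is.null(space))
    space <- scaled_search_space(b0, geom, estimate_delta(b0, geom))

  configs <- list()
  if ("tuned" %in% plan$methods) {
    colony <- plan$colony
    colony$seed <- plan$seed
    tune <- aco_tune(b0, geom, truth, space, colony, final_recon = FALSE)
    configs$tuned <- tune$best_config$values
  }
  if ("cv" %in% plan$methods) {
    cvres <- cv_tune(b0, geom, space, trial_stride = plan$cv_trial_stride,
                     max_iter = plan$max_iter)
    configs$cv <- cvres$best_config$values
  }
  if ("arbitrary" %in% plan$methods) configs$arbitrary <- plan$arbitrary

  rows <- list(); images <- list(); profiles <- list(); diffs <- list()
  mid <- ceiling(plan$grid_shape[2] / 2)
  for (case in names(projs)) {
    b <- projs[[case]]
    images[[case]] <- list(); diffs[[case]] <- list()
    profiles[[case]] <- list(truth = truth[, mid])
    for (m in plan$methods) {
      img <- NULL; status <- "ok"
      err <- tryCatch({
        img <- if (m == "cgls")
          cgls(b, geom, n_iter = plan$max_iter)
        else
          awpcsd_config_recon(configs[[m]], b, geom, space$fixed,
                              plan$max_iter)
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(err)) status <- paste0("failed: ", err)
      met <- if (is.null(img)) list(cc = NA_real_, uqi = NA_real_,
                                    relative_error = NA_real_)
             else metric_report(img, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        case = case, method = m,
        epsilon = if (m == "cgls") NA_real_ else configs[[m]]$epsilon,
        ng = if (m == "cgls") NA_real_ else as.numeric(configs[[m]]$ng),
        relative_error_pct = 100 * met$relative_error,
        uqi = met$uqi, cc = met$cc, status = status)
      if (!is.null(img)) {
        images[[case]][[m]] <- img
        diffs[[case]][[m]] <- img - truth
        profiles[[case]][[m]] <- img[, mid]
      }
    }
  }
  structure(list(table = do.call(rbind, rows), images = images,
                 profiles = profiles, diff_images = diffs,
                 truth = truth, configs = configs, space = space,
                 plan = plan),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  print(x$table[, c("case", "method", "relative_error_pct", "uqi")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Transfer experiment: trained hyperparameters on a different sample
#'
#' Applies a hyperparameter configuration trained on one phantom to a
#' different phantom variant and compares it against tuning directly on
#' the new sample, the arbitrary setting, and CGLS.
#'
#' @param trained_config list with `epsilon` and `ng` obtained on the
#'   training sample.
#' @param plan an [experiment_plan()] whose `phantom_variant` names the
#'   new sample; only its first (default) noise case is used.
#' @return a `comparison_result` whose table rows are the methods
#'   `trained`, `tuned` (directly tuned on the new sample), `arbitrary`
#'   and `cgls` on the new phantom.
#' @export
transfer_experiment <- function(trained_config, plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  geom <- plan_geometry(plan)
  truth <- render_phantom(thorax_phantom_spec(plan$grid_shape,
                                              plan$phantom_variant))
  b <- plan_noisy_projections(plan, truth, geom)[[1L]]
  space <- plan$space
  if (is.null(space))
    space <- scaled_search_space(b, geom, estimate_delta(b, geom))

  colony <- plan$colony
  colony$seed <- plan$seed
  tune <- aco_tune(b, geom, truth, space, colony, final_recon = FALSE)
  configs <- list(trained = trained_config,
                  tuned = tune$best_config$values,
                  arbitrary = plan$arbitrary)
  rows <- list(); images <- list()
  for (m in c("trained", "tuned", "arbitrary", "cgls")) {
    img <- NULL; status <- "ok"
    err <- tryCatch({
      img <- if (m == "cgls") cgls(b, geom, n_iter = plan$max_iter)
             else awpcsd_config_recon(configs[[m]], b, geom, space$fixed,
                                      plan$max_iter)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(err)) status <- paste0("failed: ", err)
    met <- if (is.null(img)) list(cc = NA_real_, uqi = NA_real_,
                                  relative_error = NA_real_)
           else metric_report(img, truth)
    rows[[length(rows) + 1L]] <- data.frame(
      case = plan$phantom_variant, method = m,
      epsilon = if (m == "cgls") NA_real_ else configs[[m]]$epsilon,
      ng = if (m == "cgls") NA_real_ else as.numeric(configs[[m]]$ng),
      relative_error_pct = 100 * met$relative_error,
      uqi = met$uqi, cc = met$cc, status = status)
    if (!is.null(img)) images[[m]] <- img
  }
  structure(list(table = do.call(rbind, rows), images = images,
                 truth = truth, configs = configs, space = space,
                 plan = plan),
            class = "comparison_result")
}
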