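#' Experiment configuration
#'
#' Validated bundle of all design parameters of a simulated experiment.
#' Defaults mirror the full design: three categories, 25 sessions of 48
#' trials each (12 easy + 24 difficult baseline, 12 test), Gaussian noise
#' with mean 128 and SD 30, opacities 0.50 (easy) and 0.20 (difficult),
#' FDR level 0.05.
#'
#' @param categories character vector of stimulus categories.
#' @param n_sessions sessions per category.
#' @param n_participants simulated participants per category.
#' @param composition per-session trial counts
#'   `c(easy = , difficult = , test = )`.
#' @param noise_mean,noise_sd noise parameters (0-255 luminance scale).
#' @param opacity `c(easy = , difficult = )` blend fractions in \[0, 1\].
#' @param geometry a [stim_geometry()].
#' @param q FDR level in (0, 1).
#' @param seed master seed; all stage seeds are derived from it.
#' @param n_null number of random-selection null replicates to run per
#'   category (0 disables).
#' @param observer optional [observer()]; by default a template matcher
#'   whose template is the mean of the category's target bank.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(categories = c("chimpanzee_face", "human_face",
                                             "letter"),
                              n_sessions = 25, n_participants = 1,
                              composition = c(easy = 12, difficult = 24,
                                              test = 12),
                              noise_mean = 128, noise_sd = 30,
                              opacity = c(easy = 0.5, difficult = 0.2),
                              geometry = stim_geometry(), q = 0.05,
                              seed = 1, n_null = 0, observer = NULL) {
  stopifnot(length(categories) >= 1, n_sessions >= 1, n_participants >= 1)
  if (!all(c("easy", "difficult", "test") %in% names(composition))) {
    stop("composition needs counts for easy, difficult and test",
         call. = FALSE)
  }
  if (any(composition < 0) || composition[["test"]] < 1) {
    stop("invalid session composition", call. = FALSE)
  }
  if (q <= 0 || q >= 1) stop("q must lie strictly inside (0, 1)",
                             call. = FALSE)
  if (any(opacity < 0) || any(opacity > 1)) {
    stop("opacities must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(categories = categories, n_sessions = n_sessions,
                 n_participants = n_participants,
                 composition = composition, noise_mean = noise_mean,
                 noise_sd = noise_sd, opacity = opacity,
                 geometry = geometry, q = q, seed = seed, n_null = n_null,
                 observer = observer),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration\n")
  cat(sprintf("  categories : %s\n", paste(x$categories, collapse = ", ")))
  cat(sprintf("  sessions   : %d x %d trials (easy %d, difficult %d, test %d)\n",
              x$n_sessions, sum(x$composition), x$composition[["easy"]],
              x$composition[["difficult"]], x$composition[["test"]]))
  cat(sprintf("  noise N(%g, %g); opacity easy %.2f / difficult %.2f; q = %g; seed %d\n",
              x$noise_mean, x$noise_sd, x$opacity[["easy"]],
              x$opacity[["difficult"]], x$q, x$seed))
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()];
#' `geometry` may be a mapping of [stim_geometry()] arguments.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$geometry)) y$geometry <- do.call(stim_geometry, y$geometry)
  for (nm in c("composition", "opacity")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  do.call(experiment_config, y)
}

#' Run the full simulate-analyze-report pipeline
#'
#' For every category: plans and runs the experiment for each simulated
#' participant, writes the trial log, builds the reverse-correlation
#' dataset, writes the classification image (enhanced PNGs plus raw
#' difference plane), fits the per-pixel map with FDR control and writes
#' its CSV and heatmap, optionally runs random-selection null replicates,
#' computes position-bias statistics, and finally emits a JSON report
#' with the seed and a configuration hash.  Byte-identical outputs are
#' produced for identical configurations.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output directory is not empty (use overwrite = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config$geometry
  aoi <- default_aoi(geom)
  report <- list(seed = config$seed,
                 config_hash = config_hash(config[setdiff(names(config),
                                                          "observer")]),
                 categories = list())
  diff_planes <- list()
  for (cat in config$categories) {
    cat_dir <- file.path(out_dir, cat)
    dir.create(cat_dir, showWarnings = FALSE)
    cat_seed <- derive_seed(config$seed, cat)
    obs <- config$observer %||% observer(
      bank_mean(make_target_bank(cat, seed = derive_seed(cat_seed, "bank"),
                                 width = geom$target_w,
                                 height = geom$target_h)))
    sim <- simulate_cohort(config$n_participants, cat, config$n_sessions,
                           obs, geometry = geom, seed = cat_seed,
                           composition = config$composition,
                           opacity = config$opacity,
                           noise_mean = config$noise_mean,
                           noise_sd = config$noise_sd)
    write_trial_log(sim$log, file.path(cat_dir, "trial_log.csv"))
    ds <- build_choice_dataset(sim$log, sim$store, aoi = aoi)
    ci <- classification_image(ds)
    write_classification_image(ci, cat_dir, prefix = "ci")
    map <- fit_pixel_map(ds, q = config$q)
    write_pixel_map_csv(map, file.path(cat_dir, "pixel_map.csv"))
    write_heatmap_png(map, file.path(cat_dir, "heatmap_pfdr.png"))
    null_sig <- NULL
    if (config$n_null > 0) {
      null_sig <- vapply(seq_len(config$n_null), function(r) {
        nmap <- fit_pixel_map(
          random_selection_null(ds, seed = derive_seed(cat_seed,
                                                       paste0("null", r))),
          q = config$q)
        sum(nmap$sig)
      }, numeric(1))
      utils::write.csv(data.frame(replicate = seq_along(null_sig),
                                  n_significant = null_sig),
                       file.path(cat_dir, "null_calibration.csv"),
                       row.names = FALSE)
    }
    bias <- position_bias_chisq(sim$log)
    utils::write.csv(bias, file.path(cat_dir, "position_bias.csv"),
                     row.names = FALSE)
    diff_planes[[cat]] <- ci$difference
    report$categories[[cat]] <- list(
      n_test_trials = n_trials(ds),
      n_correction_trials = sum(sim$log$is_correction),
      reward_rate_test = mean(ds$trials$rewarded),
      aoi_mean_difference = mean(crop_aoi(ci$difference, aoi)),
      n_significant_pixels = sum(map$sig),
      n_singular_pixels = map$n_singular,
      null_replicates_with_signal = if (!is.null(null_sig))
        sum(null_sig > 0) else NA)
  }
  if (length(diff_planes) >= 2) {
    bdm <- brightness_difference_model(diff_planes, aoi = aoi)
    utils::write.csv(bdm$summary, file.path(out_dir, "brightness_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(bdm$contrasts,
                     file.path(out_dir, "brightness_contrasts.csv"),
                     row.names = FALSE)
    report$brightness <- list(summary = bdm$summary,
                              contrasts = bdm$contrasts)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Miniature self-contained experiments for tests and examples
#'
#' Generates a complete down-scaled experiment in memory: a proportional
#' geometry (tiny: 30 x 34 canvas with a 20 x 22 AOI; small: 74 x 83
#' canvas with a 50 x 55 AOI), a procedural target bank, a
#' template-matching observer and a simulated cohort, returning the log,
#' stimulus store and assembled `choice_dataset`.
#'
#' The default fixture observer is an idealized template matcher
#' (`beta = 50`, no lapses) whose response times are strongly coupled to
#' the evidence (`rt_sd = 30` ms against an evidence term of comparable
#' size), so that evidence-dependent response-time properties are
#' visible at fixture scale.
#'
#' @param scale `"tiny"` (30 test trials) or `"small"` (100 test
#'   trials).
#' @param seed master seed.
#' @param n_trials override the number of test trials (sessions are
#'   extended and the dataset trimmed to exactly this count).
#' @param n_participants simulated participants.
#' @param category stimulus category.
#' @param obs optional [observer()] overriding the fixture default.
#' @return List: `geometry`, `aoi`, `bank`, `template`, `observer`,
#'   `log`, `store`, `dataset`, `composition`.
#' @export
make_fixtures <- function(scale = c("tiny", "small"), seed = 1,
                          n_trials = NULL, n_participants = 1,
                          category = "human_face", obs = NULL) {
  scale <- match.arg(scale)
  geom <- if (scale == "tiny") {
    stim_geometry(canvas_w = 30, canvas_h = 34, target_w = 20,
                  target_h = 22, ellipse_w = 24, ellipse_h = 28,
                  frame_stroke = 1, cross_size = 2, cross_thickness = 1)
  } else {
    stim_geometry(canvas_w = 74, canvas_h = 83, target_w = 50,
                  target_h = 55, ellipse_w = 59, ellipse_h = 70,
                  frame_stroke = 2, cross_size = 4, cross_thickness = 2)
  }
  composition <- if (scale == "tiny") {
    c(easy = 2, difficult = 4, test = 6)
  } else {
    c(easy = 2, difficult = 4, test = 10)
  }
  target_trials <- n_trials %||% (if (scale == "tiny") 30L else 100L)
  per_part <- ceiling(target_trials / n_participants)
  n_sessions <- ceiling(per_part / composition[["test"]])
  bank <- make_target_bank(category, n = 20,
                           seed = derive_seed(seed, "bank"),
                           width = geom$target_w, height = geom$target_h)
  template <- bank_mean(bank)
  obs <- obs %||% observer(template, beta = 50, lapse = 0,
                           rt_base = 1300, rt_slope = 1200, rt_sd = 30)
  sim <- simulate_cohort(n_participants, category, n_sessions, obs,
                         geometry = geom, seed = derive_seed(seed, "sim"),
                         composition = composition)
  ds <- build_choice_dataset(sim$log, sim$store, aoi = default_aoi(geom))
  if (n_trials(ds) > target_trials) {
    keep <- unlist(lapply(split(seq_len(n_trials(ds)),
                                ds$trials$participant),
                          utils::head, n = ceiling(target_trials /
                                                     n_participants)))
    ds <- ds[sort(keep)[seq_len(min(target_trials, length(keep)))]]
  }
  list(geometry = geom, aoi = default_aoi(geom), bank = bank,
       template = template, observer = obs, log = sim$log,
       store = sim$store, dataset = ds, composition = composition)
}
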