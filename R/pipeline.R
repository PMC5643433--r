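#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis pipeline: the study
#' design, the preprocessing thresholds (60 Hz gaze grid, 20-frame closure
#' limit, 100 ms / 2 degree fixation criteria, 60 s feature window, 120 s
#' vital-sign interval), the questionnaire midpoint, the model-selection
#' alpha, and the seed. Configurations round-trip losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param n_participants,n_videos,video_duration,gaze_rate,vital_interval,seed
#'   study design, see [study_design()].
#' @param max_closed_frames longest retained eye-closure run (frames).
#' @param min_fix_duration_ms,max_dispersion_deg I-DT fixation criteria.
#' @param window_s,step_s feature window length and step (seconds).
#' @param midpoint questionnaire midpoint.
#' @param alpha significance level for random-effect selection.
#' @param out_dir output directory for [run_pipeline()] artifacts.
#' @return A list of class `icuvr_config`.
#' @export
pipeline_config <- function(n_participants = 37, n_videos = 3,
                            video_duration = 300, gaze_rate = 60,
                            vital_interval = 120, seed = 1L,
                            max_closed_frames = 20,
                            min_fix_duration_ms = 100,
                            max_dispersion_deg = 2,
                            window_s = 60, step_s = 1 / 60,
                            midpoint = 2.5, alpha = 0.05,
                            out_dir = "icuvr-run") {
  cfg <- list(n_participants = n_participants, n_videos = n_videos,
              video_duration = video_duration, gaze_rate = gaze_rate,
              vital_interval = vital_interval, seed = as.integer(seed),
              max_closed_frames = max_closed_frames,
              min_fix_duration_ms = min_fix_duration_ms,
              max_dispersion_deg = max_dispersion_deg,
              window_s = window_s, step_s = step_s, midpoint = midpoint,
              alpha = alpha, out_dir = out_dir)
  num <- setdiff(names(cfg), "out_dir")
  for (nm in setdiff(num, "seed"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(sprintf("config field '%s' must be positive", nm), call. = FALSE)
  class(cfg) <- "icuvr_config"
  cfg
}

#' A small demonstration configuration
#'
#' Scaled-down study (6 participants, 120 s videos, 1 s feature step) so
#' the full pipeline runs in seconds.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return An `icuvr_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("icuvr-demo")) {
  pipeline_config(n_participants = 6, video_duration = 120,
                  vital_interval = 60, step_s = 1, window_s = 60,
                  seed = seed, out_dir = out_dir)
}

#' @rdname pipeline_config
#' @param config an `icuvr_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a study and runs every stage: gaze simulation,
#' event parsing and windowed features, the eight-model oculomotor suite
#' for all four features, vital-sign simulation, two-minute medians, the
#' begin/middle/end analysis grid, the random-effects model ladder for the
#' four vital signs, Holm-adjusted rating effects, and the questionnaire
#' midpoint tests. All intermediate tables are written as CSV, model
#' results as JSON, and a manifest (config hash, seed, package version)
#' sufficient to reproduce the run.
#'
#' @param config an `icuvr_config`, e.g. [demo_config()].
#' @param gaze_csv,vitals_csv,questionnaire_csv optional paths to existing
#'   input tables (analyze mode); when `NULL` the stage simulates its
#'   input from the config.
#' @param quiet suppress progress messages.
#' @return A run report (list) with the feature table, model suites,
#'   vitals ladders, rating effects and questionnaire tests, invisibly.
#' @examples
#' \donttest{
#' rep <- run_pipeline(demo_config(seed = 42))
#' names(rep)
#' }
#' @export
run_pipeline <- function(config = demo_config(), gaze_csv = NULL,
                         vitals_csv = NULL, questionnaire_csv = NULL,
                         quiet = FALSE) {
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- study_design(n_participants = config$n_participants,
                         n_videos = config$n_videos,
                         video_duration = config$video_duration,
                         gaze_rate = config$gaze_rate,
                         vital_interval = config$vital_interval,
                         seed = config$seed)

  # --- gaze ---------------------------------------------------------------
  if (is.null(gaze_csv)) {
    say("simulating gaze traces ...")
    gaze <- simulate_gaze_study(design, seed = config$seed)$samples
  } else {
    if (!file.exists(gaze_csv))
      stop(sprintf("config field 'gaze_csv': file '%s' not found", gaze_csv),
           call. = FALSE)
    gaze <- read.csv(gaze_csv)
  }
  write.csv(gaze, file.path(config$out_dir, "gaze_samples.csv"),
            row.names = FALSE)
  say("parsing events and extracting windowed features ...")
  features <- extract_gaze_features(
    gaze, rate_hz = config$gaze_rate,
    max_closed_frames = config$max_closed_frames,
    min_duration_ms = config$min_fix_duration_ms,
    max_dispersion_deg = config$max_dispersion_deg,
    window_s = config$window_s, step_s = config$step_s)
  features$time_global <- (features$video - 1) * config$video_duration +
    features$t
  features$video_type <- factor(features$video)
  write.csv(features, file.path(config$out_dir, "gaze_features.csv"),
            row.names = FALSE)

  say("fitting the eight-model oculomotor suite ...")
  resp <- c("n_fix_per_s", "fix_dur_ms_per_s", "sacc_amp_deg",
            "fix_sacc_ratio")
  suites <- lapply(setNames(resp, resp), function(r)
    oculomotor_model_suite(features, r))

  # --- vitals -------------------------------------------------------------
  if (is.null(vitals_csv)) {
    say("simulating vital signs ...")
    set.seed(config$seed)
    ages <- round(runif(config$n_participants, 20, 85))
    vitals_raw <- simulate_vitals(design, ages = ages,
                                  raw_interval_s = 10, seed = config$seed)
  } else {
    if (!file.exists(vitals_csv))
      stop(sprintf("config field 'vitals_csv': file '%s' not found",
                   vitals_csv), call. = FALSE)
    vitals_raw <- read.csv(vitals_csv)
  }
  write.csv(vitals_raw, file.path(config$out_dir, "vitals_raw.csv"),
            row.names = FALSE)
  med <- two_minute_medians(vitals_raw, interval_s = config$vital_interval,
                            t_max = config$n_videos * config$video_duration)
  sched <- data.frame(video_index = seq_len(config$n_videos),
                      start_s = (seq_len(config$n_videos) - 1) *
                        config$video_duration,
                      end_s = seq_len(config$n_videos) *
                        config$video_duration)
  grid <- to_analysis_grid(med, sched)
  grid$video_type <- factor(grid$video_index)
  write.csv(grid, file.path(config$out_dir, "vitals_grid.csv"),
            row.names = FALSE)

  say("selecting vitals models (ladder) ...")
  vit <- c("hf", "map", "rf", "spo2")
  ladders <- lapply(setNames(vit, vit), function(r)
    select_vitals_model(grid, r, fixed = c("time_index", "video_type"),
                        alpha = config$alpha))

  # --- questionnaire ------------------------------------------------------
  if (is.null(questionnaire_csv)) {
    say("simulating questionnaire responses ...")
    items <- simulate_questionnaire_items(n = config$n_participants,
                                          n_videos = config$n_videos,
                                          seed = config$seed)
  } else {
    if (!file.exists(questionnaire_csv))
      stop(sprintf("config field 'questionnaire_csv': file '%s' not found",
                   questionnaire_csv), call. = FALSE)
    items <- read.csv(questionnaire_csv)
  }
  scores <- score_scales(items)
  qtests <- questionnaire_tests(scores, midpoint = config$midpoint)
  write.csv(qtests, file.path(config$out_dir, "questionnaire_tests.csv"),
            row.names = FALSE)

  say("adding Holm-adjusted rating effects to the chosen vitals models ...")
  rating_effects <- lapply(ladders, function(l)
    add_rating_effects(l, scores, grid))

  # --- report & manifest --------------------------------------------------
  report <- list(
    features = features,
    oculomotor_suites = lapply(suites, function(s)
      s[c("models", "delta_r2")]),
    vitals_ladders = lapply(ladders, function(l)
      list(chosen_model = l$chosen_model, ladder = l$ladder,
           beta = l$chosen$beta, r2 = l$chosen$r2)),
    rating_effects = rating_effects,
    questionnaire = qtests)
  jsonlite::write_json(report[c("oculomotor_suites", "vitals_ladders",
                                "rating_effects", "questionnaire")],
                       file.path(config$out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package_version = as.character(packageVersion("icuvr")),
                   r_version = R.version.string,
                   elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  say("done in %.1f s; artifacts in %s", manifest$elapsed_s, config$out_dir)
  invisible(report)
}
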