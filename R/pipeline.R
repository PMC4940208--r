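#' Experiment orchestration
#'
#' One configuration object carries every tunable of the pipeline; a single
#' top-level seed fans out deterministically to the session generator, the
#' network initializations and the test-target draws, so
#' simulate -> train -> evaluate is bit-reproducible. The `cmd_*` functions
#' are the programmatic equivalents of the shell subcommands exposed by the
#' `inst/cli/myoreach` script.
#'
#' @name pipeline
NULL

#' Default experiment configuration
#'
#' Defaults reproduce the stated protocol: 1000 Hz EMG band-limited
#' 15-450 Hz, 50 Hz IMU, 150 ms conditioning windows on a 50 ms frame grid,
#' taps {0,1,2,3}, training tolerances 4 deg (flexion/extension) and 8 deg
#' (pronation/supination) starting from 6 hidden units, 5 cm / 30 deg /
#' 0.5 s acquisition, 10 cm targets, 64 preset training targets, ten 30 s
#' test trials in a 2 cm margin-shrunk workspace.
#'
#' @param seed top-level integer seed.
#' @param overrides named list of fields to replace.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1, overrides = list()) {
  cfg <- list(
    seed = seed,
    reach_duration = 4, return_duration = 4, hold_duration = 0.5,
    imu_rate = 50, frame_period = 0.05,
    lags = c(0, 1, 2, 3),
    tol_flexion = 4, tol_pronation = 8,
    init_hidden = 6, max_hidden = 20,
    pos_tol = 5, ori_tol = 30, hold = 0.5, target_size = 10,
    n_trials = 10, trial_len = 30, shrink_margin = 2,
    corr_gain = 0.3, tau_hand = 2,
    noise_floor = 0.05, envelope_jitter = 0.05)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "experiment_config")
}

#' Load a configuration from YAML
#'
#' @param path YAML file with any subset of [experiment_config()] fields.
#' @param seed optional seed override.
#' @return `experiment_config`.
#' @export
read_config <- function(path, seed = NULL) {
  ov <- yaml::read_yaml(path)
  use_seed <- if (!is.null(seed)) seed
              else if (!is.null(ov$seed)) ov$seed else 1
  ov$seed <- NULL
  experiment_config(seed = use_seed, overrides = ov)
}

cfg_emg <- function(cfg) emg_synth_config(noise_floor = cfg$noise_floor,
                                          envelope_jitter = cfg$envelope_jitter)

cfg_rule <- function(cfg) acquisition_rule(cfg$pos_tol, cfg$ori_tol,
                                           cfg$hold)

#' Generate and write one synthetic training session
#'
#' Runs the preset 64-target protocol for one synthetic subject and writes
#' `emg.csv`, `imu.csv` and `session.json` to `out_dir`.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return the `sensor_streams` object, invisibly.
#' @export
cmd_simulate <- function(cfg = experiment_config(), out_dir = NULL) {
  subject <- arm_model()
  targets <- preset_training_targets(size = cfg$target_size)
  streams <- run_protocol_session(subject, targets, cfg_emg(cfg),
                                  reach_duration = cfg$reach_duration,
                                  return_duration = cfg$return_duration,
                                  hold_duration = cfg$hold_duration,
                                  imu_rate = cfg$imu_rate,
                                  seed = cfg$seed)
  if (!is.null(out_dir)) write_session(streams, out_dir)
  invisible(streams)
}

#' Read a written session back into a `sensor_streams` object
#'
#' @param dir directory holding `emg.csv`, `imu.csv`, `session.json`.
#' @return `sensor_streams`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  emg <- utils::read.csv(file.path(dir, "emg.csv"))
  imu <- utils::read.csv(file.path(dir, "imu.csv"))
  cfg <- emg_synth_config(n_channels = meta$emg$n_channels,
                          carrier_band = meta$emg$carrier_band,
                          sample_rate = meta$emg$sample_rate,
                          mixing_matrix = matrix(
                            unlist(meta$emg$mixing_matrix),
                            meta$emg$n_channels, 4),
                          noise_floor = meta$emg$noise_floor,
                          envelope_jitter = meta$emg$envelope_jitter)
  truth <- data.frame(t = imu$t, flexion = imu$truth_flexion,
                      pronation = imu$truth_pronation,
                      target_id = imu$target_id, segment = imu$segment)
  structure(list(t_imu = imu$t,
                 gyro = as.matrix(imu[, c("gyro_x", "gyro_y", "gyro_z")]),
                 accel = as.matrix(imu[, c("accel_x", "accel_y",
                                           "accel_z")]),
                 truth = truth,
                 t_emg = emg$t, emg = as.matrix(emg[, -1]),
                 imu_rate = meta$imu_rate, emg_cfg = cfg,
                 seed = meta$seed),
            class = "sensor_streams")
}

#' Condition a session and train both networks
#'
#' Builds the 50 ms feature frames, delay-stacks them, trains the
#' flexion/extension and pronation/supination networks under their
#' tolerances, and (optionally) writes the two model JSON files plus a
#' training report.
#'
#' @param streams a `sensor_streams` session (or a directory path to read
#'   with [read_session()]).
#' @param cfg an [experiment_config()].
#' @param out_dir optional output directory for `model_flexion.json`,
#'   `model_pronation.json`, `train_report.json`.
#' @return list: `flexion`, `pronation` (each `model` + `report`), `X`,
#'   `frames`.
#' @export
cmd_train <- function(streams, cfg = experiment_config(), out_dir = NULL) {
  if (is.character(streams)) streams <- read_session(streams)
  fr <- feature_frames(streams, frame_period = cfg$frame_period)
  X <- stack_delays(fr$features, cfg$lags)
  keep <- (max(cfg$lags) + 1):length(fr$t)
  y_flex <- fr$truth[keep, "flexion"]
  y_pron <- fr$truth[keep, "pronation"]
  flex <- tdnn_train(X, y_flex, cfg$tol_flexion,
                     init_hidden = cfg$init_hidden,
                     max_hidden = cfg$max_hidden,
                     seed = cfg$seed + 101, target_name = "flexion",
                     lags = cfg$lags)
  pron <- tdnn_train(X, y_pron, cfg$tol_pronation,
                     init_hidden = cfg$init_hidden,
                     max_hidden = cfg$max_hidden,
                     seed = cfg$seed + 202, target_name = "pronation",
                     lags = cfg$lags)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tdnn_save(flex$model, file.path(out_dir, "model_flexion.json"))
    tdnn_save(pron$model, file.path(out_dir, "model_pronation.json"))
    jsonlite::write_json(
      list(flexion = unclass(flex$report),
           pronation = unclass(pron$report)),
      file.path(out_dir, "train_report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(flexion = flex, pronation = pron, X = X, frames = fr)
}

#' Run the closed-loop test phase and compute the metrics report
#'
#' @param flex_model,pron_model trained `tdnn_model`s (or file paths).
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory for `metrics.json` and per-trial tick
#'   CSVs.
#' @return list: `logs`, `report`.
#' @export
cmd_evaluate <- function(flex_model, pron_model,
                         cfg = experiment_config(), out_dir = NULL) {
  if (is.character(flex_model)) flex_model <- tdnn_load(flex_model)
  if (is.character(pron_model)) pron_model <- tdnn_load(pron_model)
  subject <- arm_model()
  targets <- random_test_targets(200, seed = cfg$seed + 303,
                                 shrink_margin = cfg$shrink_margin,
                                 size = cfg$target_size)
  logs <- run_ann_phase(subject, flex_model, pron_model, targets,
                        n_trials = cfg$n_trials,
                        trial_len = cfg$trial_len, mode = "ann",
                        rule = cfg_rule(cfg), emg_cfg = cfg_emg(cfg),
                        corr_gain = cfg$corr_gain, tau_hand = cfg$tau_hand,
                        lags = cfg$lags, seed = cfg$seed + 404)
  report <- metrics_report(logs, W = cfg$target_size, online = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    for (i in seq_along(logs)) {
      utils::write.csv(logs[[i]]$ticks,
                       file.path(out_dir, sprintf("trial_%02d.csv", i)),
                       row.names = FALSE)
    }
  }
  list(logs = logs, report = report)
}

#' Full pipeline: simulate, train, evaluate
#'
#' @param seed top-level seed.
#' @param out_dir optional run directory (`session/`, `models/`,
#'   `eval/`).
#' @param cfg an [experiment_config()]; its seed is replaced by `seed`.
#' @return list: `streams`, `training`, `evaluation`, `imu_phase_log`.
#' @export
run_all <- function(seed = 1, out_dir = NULL,
                    cfg = experiment_config(seed = seed)) {
  cfg$seed <- seed
  streams <- cmd_simulate(cfg, if (!is.null(out_dir))
    file.path(out_dir, "session"))
  targets <- preset_training_targets(size = cfg$target_size)
  imu_log <- run_imu_phase(streams, targets, cfg_rule(cfg))
  training <- cmd_train(streams, cfg,
                        out_dir = if (!is.null(out_dir))
                          file.path(out_dir, "models"))
  evaluation <- cmd_evaluate(training$flexion$model,
                             training$pronation$model, cfg,
                             out_dir = if (!is.null(out_dir))
                               file.path(out_dir, "eval"))
  list(streams = streams, imu_phase_log = imu_log,
       training = training, evaluation = evaluation)
}
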