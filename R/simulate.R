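#' Synthetic subject: reach planning and sensor-stream synthesis
#'
#' The simulator stands in for a human participant. It plans minimum-jerk
#' reaching movements between rest and targets, produces ground-truth segment
#' orientations, and synthesizes the raw sensor streams the controller
#' consumes: six surface-EMG channels (band-limited 15-450 Hz, 1000 Hz) whose
#' amplitudes are co-modulated with the elbow/forearm kinematics, and the 3D
#' angular velocity and linear acceleration of a humerus-mounted inertial
#' unit at 50 Hz.
#'
#' @name simulate
NULL

#' EMG synthesis configuration
#'
#' Each channel is band-passed unit-RMS white noise amplitude-modulated by a
#' non-negative envelope: `envelope = mixing_matrix %*% latents +
#' noise_floor`, where the K = 4 latent "muscle" activations are
#' deterministic rectified-linear functions of elbow flexion angle/velocity
#' and pronation angle/velocity. Latent 1 is biceps-like (co-activated by
#' flexion and supination), latent 2 triceps-like (extension velocity),
#' latent 3 supination-specific (so 30 vs 90 deg targets are separable), and
#' latent 4 a brachialis-like pure elbow flexor. Envelopes carry slow
#' multiplicative jitter (trial-to-trial variability) and the modulated
#' signal carries an additive noise floor.
#'
#' @param n_channels number of electrodes (6).
#' @param carrier_band band-pass edges, Hz.
#' @param sample_rate EMG sampling rate, Hz.
#' @param mixing_matrix `n_channels` x 4 non-negative gain matrix from
#'   latent activations to electrode envelopes (rows = channels).
#' @param noise_floor additive envelope offset, fraction of full scale.
#' @param envelope_jitter s.d. of the slow multiplicative envelope noise.
#' @return object of class `emg_synth_config`.
#' @export
emg_synth_config <- function(n_channels = 6,
                             carrier_band = c(15, 450),
                             sample_rate = 1000,
                             mixing_matrix = NULL,
                             noise_floor = 0.05,
                             envelope_jitter = 0.05) {
  if (is.null(mixing_matrix)) {
    mixing_matrix <- rbind(
      c(1.0, 0.0, 0.1, 0.2),   # over the biceps
      c(0.1, 1.0, 0.0, 0.1),   # over the triceps
      c(0.2, 0.1, 1.0, 0.0),   # supination-sensitive site
      c(0.1, 0.0, 0.1, 1.0),   # brachialis-like site
      c(0.6, 0.4, 0.0, 0.2),   # intermediate electrode (cross-talk)
      c(0.0, 0.3, 0.5, 0.4))   # intermediate electrode (cross-talk)
  }
  stopifnot(nrow(mixing_matrix) == n_channels, ncol(mixing_matrix) == 4,
            all(mixing_matrix >= 0),
            carrier_band[1] > 0, carrier_band[2] < sample_rate / 2,
            carrier_band[1] < carrier_band[2],
            noise_floor >= 0, noise_floor < 1)
  structure(list(n_channels = n_channels, carrier_band = carrier_band,
                 sample_rate = sample_rate, mixing_matrix = mixing_matrix,
                 noise_floor = noise_floor,
                 envelope_jitter = envelope_jitter),
            class = "emg_synth_config")
}

relu <- function(x) pmax(x, 0)

# linear-phase FIR band-pass used for the EMG carrier (flat 15-450 Hz band)
emg_carrier_fir <- function(band, fs, order = 120) {
  as.numeric(signal::fir1(order, band / (fs / 2), type = "pass"))
}

#' Latent muscle activations from elbow/forearm kinematics
#'
#' Deterministic rectified-linear drive for the four latent "muscles".
#' Angles in degrees, velocities in deg/s; normalization scales (150 deg
#' flexion range, 60 deg task pronation range, 200 deg/s velocity scale) are
#' fixed.
#'
#' @param flexion,pronation angle streams, deg.
#' @param flexion_vel,pronation_vel velocity streams, deg/s.
#' @return T x 4 matrix of non-negative activations.
#' @export
latent_activations <- function(flexion, pronation, flexion_vel,
                               pronation_vel) {
  fn <- flexion / 150
  pn <- (90 - pronation) / 60          # supination drive: 1 at palm-up (30)
  fv <- flexion_vel / 200
  pv <- pronation_vel / 200
  cbind(biceps     = 0.5 * relu(fn) + 0.5 * relu(pn) + 0.3 * relu(fv),
        triceps    = 0.7 * relu(-fv) + 0.3 * relu(1 - fn),
        supinator  = 0.9 * relu(pn) + 0.3 * relu(-pv),
        brachialis = 0.9 * relu(fn) + 0.3 * relu(fv))
}

#' Synthesize the six-channel surface EMG stream
#'
#' @param flexion,pronation ground-truth angle streams at `cfg$sample_rate`,
#'   deg.
#' @param cfg an [emg_synth_config()].
#' @param envelopes optionally, a precomputed T x 4 latent matrix (overrides
#'   the kinematic drive; used by tests).
#' @return T x n_channels matrix, arbitrary mV-scale units. Reproducible
#'   under `set.seed()`; all randomness is drawn from the current RNG
#'   stream.
#' @export
synthesize_emg <- function(flexion = NULL, pronation = NULL, cfg,
                           envelopes = NULL) {
  fs <- cfg$sample_rate
  if (is.null(envelopes)) {
    fv <- c(0, diff(flexion)) * fs
    pv <- c(0, diff(pronation)) * fs
    envelopes <- latent_activations(flexion, pronation, fv, pv)
  }
  n <- nrow(envelopes)
  nch <- cfg$n_channels
  if (cfg$envelope_jitter > 0 && n > 24) {
    # slow (~1 Hz) multiplicative variability per latent
    lp <- signal::butter(2, 2 / fs * 2, type = "low")
    z <- apply(matrix(stats::rnorm(n * ncol(envelopes)), n), 2, function(w) {
      w <- as.numeric(signal::filter(lp, w))
      w / max(stats::sd(w), 1e-12)
    })
    envelopes <- envelopes * (1 + cfg$envelope_jitter * z)
  }
  amp <- envelopes %*% t(cfg$mixing_matrix) + cfg$noise_floor
  amp <- pmax(amp, 0)
  # flat passband matters: a resonator-like IIR band-pass would leave the
  # carrier strongly autocorrelated and ruin 150 ms amplitude estimates
  bp <- emg_carrier_fir(cfg$carrier_band, fs)
  emg <- matrix(0, n, nch)
  for (ch in seq_len(nch)) {
    carrier <- as.numeric(signal::filter(bp, 1, stats::rnorm(n)))
    s <- stats::sd(carrier)
    if (s > 0) carrier <- carrier / s
    emg[, ch] <- amp[, ch] * carrier
  }
  colnames(emg) <- paste0("emg", seq_len(nch))
  emg
}

#' Minimum-jerk position profile
#'
#' The 10-15-6 quintic: smooth s(0)=0, s(1)=1 with zero endpoint velocity
#' and acceleration; peak rate 1.875 at the midpoint.
#'
#' @param tau normalized time in [0, 1].
#' @return normalized displacement.
#' @export
min_jerk <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Plan a reach as a joint-space trajectory
#'
#' Straight minimum-jerk hand path from the start hand position to the
#' target position, with the pronation angle interpolated along the same
#' profile; inverse kinematics ([arm_ik()]) distributes the motion over the
#' thoracohumeral and elbow degrees of freedom deterministically.
#'
#' @param model an [arm_model()].
#' @param start_q starting joint state (list as from [arm_ik()]).
#' @param target list with `position` (cm) and `pronation` (deg).
#' @param duration reach duration, s.
#' @param tick sample interval, s.
#' @return data.frame with columns `t`, the five joint angles, and hand
#'   position `hx, hy, hz` (one row per tick, including both endpoints).
#' @export
plan_reach <- function(model, start_q, target, duration, tick = 0.02) {
  stopifnot(duration > 0, tick > 0)
  p0 <- arm_fk(model, start_q)$hand
  p1 <- target$position
  pr0 <- start_q$pronation
  pr1 <- target$pronation
  tt <- seq(0, duration, by = tick)
  if (abs(tt[length(tt)] - duration) > tick / 2) tt <- c(tt, duration)
  s <- min_jerk(tt / duration)
  out <- lapply(seq_along(tt), function(i) {
    p <- p0 + s[i] * (p1 - p0)
    q <- arm_ik(model, p, pr0 + s[i] * (pr1 - pr0))
    c(t = tt[i], unlist(q), hx = p[1], hy = p[2], hz = p[3])
  })
  as.data.frame(do.call(rbind, out))
}

hold_segment <- function(q, hand, duration, tick, t0 = 0) {
  tt <- seq(tick, duration, by = tick)
  if (length(tt) == 0) return(NULL)
  hand <- unname(as.numeric(hand))
  row <- c(unlist(q), hx = hand[1], hy = hand[2], hz = hand[3])
  df <- as.data.frame(matrix(rep(row, length(tt)), nrow = length(tt),
                             byrow = TRUE))
  names(df) <- names(row)
  cbind(t = t0 + tt, df)
}

#' Run the data-collection (training) protocol for one synthetic subject
#'
#' For each target in sequence: a minimum-jerk reach from the rest posture to
#' the target, a 0.5 s hold inside it, and a return to rest. Ground-truth
#' poses are logged at the IMU rate and the full raw sensor set is
#' synthesized: EMG at 1000 Hz plus humerus gyroscope/accelerometer at
#' 50 Hz.
#'
#' @param model an [arm_model()].
#' @param targets list of targets (see [preset_training_targets()]).
#' @param emg_cfg an [emg_synth_config()].
#' @param reach_duration,return_duration,hold_duration segment durations, s.
#' @param imu_rate IMU/ground-truth sampling rate, Hz.
#' @param seed integer seed controlling all stream noise.
#' @return object of class `sensor_streams`: `t_imu`, `gyro` (T x 3, rad/s),
#'   `accel` (T x 3, m/s^2), `truth` (data.frame of joint angles and hand
#'   position per IMU tick, with `target_id` and `segment`), `t_emg`, `emg`
#'   (T1 x 6), and the configuration used.
#' @export
run_protocol_session <- function(model, targets,
                                 emg_cfg = emg_synth_config(),
                                 reach_duration = 4, return_duration = 4,
                                 hold_duration = 0.5, imu_rate = 50,
                                 seed = 1) {
  tick <- 1 / imu_rate
  rest_q <- model$rest_joints
  if (length(targets) == 0) {
    empty3 <- matrix(numeric(0), 0, 3)
    return(structure(list(t_imu = numeric(0), gyro = empty3, accel = empty3,
                          truth = data.frame(), t_emg = numeric(0),
                          emg = matrix(numeric(0), 0, emg_cfg$n_channels),
                          imu_rate = imu_rate, emg_cfg = emg_cfg,
                          seed = seed),
                     class = "sensor_streams"))
  }
  segs <- list()
  t0 <- 0
  cols <- c("t", "plane", "elevation", "axial", "flexion", "pronation",
            "hx", "hy", "hz", "segment")
  for (k in seq_along(targets)) {
    tg <- targets[[k]]
    reach <- plan_reach(model, rest_q, tg, reach_duration, tick)
    q_end <- as.list(reach[nrow(reach),
                           c("plane", "elevation", "axial", "flexion",
                             "pronation")])
    hold <- hold_segment(q_end, unlist(reach[nrow(reach),
                                             c("hx", "hy", "hz")]),
                         hold_duration, tick, t0 = reach_duration)
    ret <- plan_reach(model, q_end,
                      list(position = model$rest_hand,
                           pronation = model$rest_pronation),
                      return_duration, tick)
    ret <- ret[-1, , drop = FALSE]       # avoid duplicated boundary tick
    ret$t <- ret$t + reach_duration + hold_duration
    reach$segment <- "reach"; ret$segment <- "return"
    if (!is.null(hold)) hold$segment <- "hold"
    seg <- rbind(reach[, cols], if (!is.null(hold)) hold[, cols],
                 ret[, cols])
    seg$t <- seg$t + t0
    seg$target_id <- k
    t0 <- t0 + reach_duration + hold_duration + return_duration
    # drop the duplicated boundary tick between consecutive targets
    segs[[k]] <- if (k == 1) seg else seg[-1, , drop = FALSE]
  }
  truth <- do.call(rbind, segs)
  truth$t <- round(truth$t / tick) * tick
  rownames(truth) <- NULL
  streams_from_truth(model, truth, emg_cfg, imu_rate, seed)
}

#' Build raw sensor streams from a ground-truth joint trajectory
#'
#' @param model an [arm_model()].
#' @param truth data.frame with `t` and the five joint-angle columns sampled
#'   on the IMU tick grid.
#' @param emg_cfg an [emg_synth_config()].
#' @param imu_rate IMU rate, Hz.
#' @param seed integer seed.
#' @return `sensor_streams` object (see [run_protocol_session()]).
#' @export
streams_from_truth <- function(model, truth, emg_cfg = emg_synth_config(),
                               imu_rate = 50, seed = 1) {
  tick <- 1 / imu_rate
  n <- nrow(truth)
  if (n < 3) stop("trajectory too short")
  R_h <- lapply(seq_len(n), function(i)
    compose_thoracohumeral(truth$plane[i], truth$elevation[i],
                           truth$axial[i]))
  # backward difference: causal, like a real strapped-down gyroscope
  gyro <- matrix(0, n, 3)
  for (i in 2:n)
    gyro[i, ] <- angular_velocity(R_h[[i - 1]], R_h[[i]], tick)
  gyro[1, ] <- gyro[2, ]
  # sensor mounted mid-humerus; positions in metres for the accelerometer
  p_sens <- t(vapply(R_h, function(R)
    as.vector(R %*% c(0, -model$L1 / 2, 0)) / 100, numeric(3)))
  accel <- linear_acceleration(p_sens, R_h, tick)
  colnames(gyro) <- paste0("gyro_", c("x", "y", "z"))
  colnames(accel) <- paste0("accel_", c("x", "y", "z"))

  # EMG at the full rate, envelopes from linearly interpolated truth angles
  fs <- emg_cfg$sample_rate
  t_emg <- seq(truth$t[1], truth$t[n], by = 1 / fs)
  flex <- stats::approx(truth$t, truth$flexion, t_emg, rule = 2)$y
  pron <- stats::approx(truth$t, truth$pronation, t_emg, rule = 2)$y
  set.seed(seed %% .Machine$integer.max)
  emg <- synthesize_emg(flex, pron, emg_cfg)

  structure(list(t_imu = truth$t, gyro = gyro, accel = accel,
                 truth = truth, t_emg = t_emg, emg = emg,
                 imu_rate = imu_rate, emg_cfg = emg_cfg, seed = seed),
            class = "sensor_streams")
}

#' @export
print.sensor_streams <- function(x, ...) {
  cat(sprintf(
    "<sensor_streams> %.1f s: EMG %d ch @ %d Hz (%d samples), IMU @ %d Hz (%d samples)\n",
    diff(range(x$t_imu)), ncol(x$emg), x$emg_cfg$sample_rate, nrow(x$emg),
    x$imu_rate, length(x$t_imu)))
  invisible(x)
}

#' Write a session's streams to disk
#'
#' `emg.csv` (1000 Hz), `imu.csv` (50 Hz, includes ground-truth angle
#' columns) and `session.json` (configuration and seed).
#'
#' @param streams a `sensor_streams` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(streams, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(t = streams$t_emg, streams$emg),
                   file.path(dir, "emg.csv"), row.names = FALSE)
  imu <- data.frame(t = streams$t_imu, streams$gyro, streams$accel,
                    truth_flexion = streams$truth$flexion,
                    truth_pronation = streams$truth$pronation,
                    target_id = streams$truth$target_id,
                    segment = streams$truth$segment)
  utils::write.csv(imu, file.path(dir, "imu.csv"), row.names = FALSE)
  meta <- list(imu_rate = streams$imu_rate, seed = streams$seed,
               emg = list(n_channels = streams$emg_cfg$n_channels,
                          carrier_band = streams$emg_cfg$carrier_band,
                          sample_rate = streams$emg_cfg$sample_rate,
                          noise_floor = streams$emg_cfg$noise_floor,
                          envelope_jitter = streams$emg_cfg$envelope_jitter,
                          mixing_matrix = streams$emg_cfg$mixing_matrix))
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
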