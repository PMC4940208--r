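#' Headless target-reaching task
#'
#' Targets live in a rectangular workspace in the shoulder frame
#' (x: -10..20 cm, y: -10..20 cm, z: -50..-40 cm, anterior = negative z)
#' and are oriented at either 30 deg (palm up) or 90 deg (neutral) of
#' pronation. A target is acquired when the virtual hand stays within 5 cm
#' of the target position and 30 deg of its orientation for a continuous
#' 0.5 s; leaving early counts as an overshoot event. The data-collection
#' phase presents a preset grid of 64 targets under ground-truth (IMU)
#' control; the test phase presents randomized targets in 30 s trials under
#' closed-loop network control with a simulated user correcting the humerus.
#'
#' @name task
NULL

WORKSPACE <- list(x = c(-10, 20), y = c(-10, 20), z = c(-50, -40))

#' Construct a reaching target
#'
#' @param position 3-vector, cm, shoulder frame.
#' @param pronation target orientation, deg (30 or 90), or `NA` to skip the
#'   orientation check (position-only acquisition).
#' @param size target width W, cm (10).
#' @return list of class `reach_target`.
#' @export
reach_target <- function(position, pronation, size = 10) {
  structure(list(position = as.numeric(position),
                 pronation = pronation, size = size),
            class = "reach_target")
}

#' Acquisition rule
#'
#' @param pos_tol position tolerance, cm (5).
#' @param ori_tol orientation tolerance, deg (30).
#' @param hold required continuous in-target time, s (0.5).
#' @return list of class `acquisition_rule`.
#' @export
acquisition_rule <- function(pos_tol = 5, ori_tol = 30, hold = 0.5) {
  stopifnot(pos_tol > 0, ori_tol > 0, hold > 0)
  structure(list(pos_tol = pos_tol, ori_tol = ori_tol, hold = hold),
            class = "acquisition_rule")
}

#' The preset 64-target training sequence
#'
#' 32 positions on a regular 4 x 4 x 2 grid spanning the workspace, each
#' presented first at 30 deg and then at 90 deg of pronation: 64 targets,
#' deterministic.
#'
#' @param workspace list with `x`, `y`, `z` range pairs, cm.
#' @param size target width, cm.
#' @return list of 64 [reach_target()]s.
#' @export
preset_training_targets <- function(workspace = WORKSPACE, size = 10) {
  grid <- expand.grid(x = seq(workspace$x[1], workspace$x[2], length.out = 4),
                      y = seq(workspace$y[1], workspace$y[2], length.out = 4),
                      z = seq(workspace$z[1], workspace$z[2], length.out = 2))
  c(lapply(seq_len(nrow(grid)), function(i)
      reach_target(as.numeric(grid[i, ]), 30, size)),
    lapply(seq_len(nrow(grid)), function(i)
      reach_target(as.numeric(grid[i, ]), 90, size)))
}

#' Random test targets from a margin-shrunk workspace
#'
#' The test workspace is shrunk by `shrink_margin` on every face so the
#' trained networks never have to extrapolate beyond the training
#' workspace.
#'
#' @param n number of targets.
#' @param seed integer seed.
#' @param shrink_margin cm removed from each face (2).
#' @param workspace training workspace.
#' @param size target width, cm.
#' @return list of [reach_target()]s.
#' @export
random_test_targets <- function(n, seed, shrink_margin = 2,
                                workspace = WORKSPACE, size = 10) {
  stopifnot(shrink_margin >= 0)
  lo <- c(workspace$x[1], workspace$y[1], workspace$z[1]) + shrink_margin
  hi <- c(workspace$x[2], workspace$y[2], workspace$z[2]) - shrink_margin
  if (any(lo >= hi)) stop("shrink_margin collapses the workspace")
  set.seed(seed %% .Machine$integer.max)
  lapply(seq_len(n), function(i) {
    p <- lo + stats::runif(3) * (hi - lo)
    reach_target(p, sample(c(30, 90), 1), size)
  })
}

#' Initialize / advance the target-acquisition state machine
#'
#' `acquisition_state()` returns a fresh state. `update_acquisition()`
#' advances it one tick: the hand is "inside" when within `pos_tol` of the
#' target position and `ori_tol` of its orientation (orientation skipped
#' when `target$pronation` is `NA`); after a continuous `hold` seconds
#' inside, an `ACQUIRED` event fires; leaving before that fires an `EXIT`
#' (overshoot) event.
#'
#' @param state list from `acquisition_state()` or a previous update.
#' @param hand_pos 3-vector, cm.
#' @param hand_pron displayed pronation, deg.
#' @param target a [reach_target()].
#' @param rule an [acquisition_rule()].
#' @param t current time, s (monotone).
#' @return updated state; `state$event` is `NA`, `"ENTER"`, `"EXIT"` or
#'   `"ACQUIRED"` for this tick, `state$inside` and `state$acquired` track
#'   status.
#' @export
update_acquisition <- function(state, hand_pos, hand_pron, target, rule, t) {
  inside <- sqrt(sum((hand_pos - target$position)^2)) <= rule$pos_tol &&
    (is.na(target$pronation) ||
       abs(hand_pron - target$pronation) <= rule$ori_tol)
  state$event <- NA_character_
  if (state$acquired) return(state)
  if (inside && !state$inside) {
    state$inside <- TRUE
    state$t_enter <- t
    state$event <- "ENTER"
  } else if (!inside && state$inside) {
    state$inside <- FALSE
    state$event <- "EXIT"
  }
  if (state$inside && t - state$t_enter >= rule$hold - 1e-9) {
    state$acquired <- TRUE
    state$event <- "ACQUIRED"
  }
  state
}

#' @rdname update_acquisition
#' @export
acquisition_state <- function() {
  list(inside = FALSE, t_enter = NA_real_, acquired = FALSE,
       event = NA_character_)
}

#' Run the acquisition machine over a ground-truth (IMU-control) session
#'
#' Replays a logged session tick by tick, applying the acquisition rule to
#' the ground-truth hand pose. Target onset is the first tick of each
#' target's reach segment; return-segment ticks are excluded from movement
#' time.
#'
#' @param streams a `sensor_streams` session from [run_protocol_session()].
#' @param targets the target list used to generate the session.
#' @param rule an [acquisition_rule()].
#' @return a `trial_log` object: `ticks` (per-tick data.frame), `events`
#'   (t, type, target_id, D), `trial_len`.
#' @export
run_imu_phase <- function(streams, targets, rule = acquisition_rule()) {
  tr <- streams$truth
  n <- nrow(tr)
  events <- list()
  state <- acquisition_state()
  cur <- 0L
  in_target <- logical(n)
  onset_hand <- NULL
  for (i in seq_len(n)) {
    if (tr$target_id[i] != cur) {
      cur <- tr$target_id[i]
      state <- acquisition_state()
      onset_hand <- c(tr$hx[i], tr$hy[i], tr$hz[i])
      events[[length(events) + 1]] <- data.frame(
        t = tr$t[i], type = "ONSET", target_id = cur,
        D = sqrt(sum((onset_hand - targets[[cur]]$position)^2)))
    }
    if (tr$segment[i] == "return") next   # completed; hand leaving is not an overshoot
    state <- update_acquisition(state, c(tr$hx[i], tr$hy[i], tr$hz[i]),
                                tr$pronation[i], targets[[cur]], rule,
                                tr$t[i])
    in_target[i] <- state$inside || state$acquired
    if (!is.na(state$event) && state$event != "ENTER")
      events[[length(events) + 1]] <- data.frame(
        t = tr$t[i], type = state$event, target_id = cur, D = NA_real_)
  }
  ticks <- data.frame(t = tr$t, hx = tr$hx, hy = tr$hy, hz = tr$hz,
                      hand_pron = tr$pronation,
                      truth_flexion = tr$flexion,
                      truth_pronation = tr$pronation,
                      pred_flexion = NA_real_, pred_pronation = NA_real_,
                      target_id = tr$target_id, in_target = in_target,
                      segment = tr$segment)
  structure(list(ticks = ticks,
                 events = do.call(rbind, events),
                 trial_len = max(tr$t) - min(tr$t)),
            class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  ev <- table(factor(x$events$type,
                     levels = c("ONSET", "EXIT", "ACQUIRED")))
  cat(sprintf(
    "<trial_log> %.1f s, %d ticks; %d targets presented, %d acquired, %d overshoots\n",
    x$trial_len, nrow(x$ticks), ev[["ONSET"]], ev[["ACQUIRED"]],
    ev[["EXIT"]]))
  invisible(x)
}

#' Closed-loop test phase (network control with a simulated user)
#'
#' Runs 30 s trials at a 100 Hz base rate (IMU sampled every 20 ms,
#' control updated every 50 ms, EMG at 1000 Hz). Each control tick the raw
#' sensor buffers are conditioned into a feature frame, delay-stacked, fed
#' to the two networks, and the smoothed predictions drive the displayed
#' (virtual) forearm. The simulated user moves the intended arm toward an
#' aim point with a first-order lag (time constant `tau_hand`, matching a
#' comfortable self-paced reach of roughly 4 s) and corrects the aim point
#' each control tick in proportion to the displayed hand error
#' (`corr_gain`) -- a stand-in for the human's visual-feedback adaptation,
#' which has no stated model. The intended (ground-truth) elbow and forearm
#' angles keep moving as the real limb would; they drive the EMG/IMU
#' synthesis and serve as the reference for online RMSE.
#'
#' With `mode = "oracle"` the displayed forearm copies the intended angles
#' exactly (no networks, no smoothing): the engine then reproduces
#' IMU-control-phase behaviour.
#'
#' @param model an [arm_model()].
#' @param flex_model,pron_model trained `tdnn_model`s (ignored for
#'   `mode = "oracle"`).
#' @param targets list of [reach_target()]s (consumed across trials in
#'   order, recycled if exhausted).
#' @param n_trials,trial_len trial count and length, s.
#' @param mode `"ann"` (closed-loop predictions) or `"oracle"`.
#' @param rule an [acquisition_rule()].
#' @param emg_cfg an [emg_synth_config()].
#' @param corr_gain aim-point correction gain per control tick (0.3).
#' @param tau_hand intended-hand first-order lag, s (2).
#' @param lags delay-stack tap set.
#' @param seed integer seed (per-session; trial noise fans out from it).
#' @return list of `trial_log` objects, one per trial.
#' @export
run_ann_phase <- function(model, flex_model = NULL, pron_model = NULL,
                          targets, n_trials = 10, trial_len = 30,
                          mode = c("ann", "oracle"),
                          rule = acquisition_rule(),
                          emg_cfg = emg_synth_config(),
                          corr_gain = 0.3, tau_hand = 2,
                          lags = c(0, 1, 2, 3), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "ann" && (is.null(flex_model) || is.null(pron_model)))
    stop("trained models required for mode = 'ann'")
  logs <- vector("list", n_trials)
  tgt_i <- 0L
  for (trial in seq_len(n_trials)) {
    res <- run_closed_loop_trial(model, flex_model, pron_model, targets,
                                 tgt_i, trial_len, mode, rule, emg_cfg,
                                 corr_gain, tau_hand, lags,
                                 seed = (seed + 1000 * trial) %%
                                   .Machine$integer.max)
    logs[[trial]] <- res$log
    tgt_i <- res$next_target_index
  }
  logs
}

run_closed_loop_trial <- function(model, flex_model, pron_model, targets,
                                  tgt_i, trial_len, mode, rule, emg_cfg,
                                  corr_gain, tau_hand, lags, seed) {
  base_dt <- 0.01                      # 100 Hz base clock
  imu_every <- 2                       # 50 Hz
  ctrl_every <- 5                      # 50 ms
  fs <- emg_cfg$sample_rate
  emg_per_tick <- round(fs * base_dt)
  n_base <- round(trial_len / base_dt)
  n_imu <- n_base %/% imu_every
  max_lag <- max(lags)

  set.seed(seed)
  # pregenerate the stochastic parts of the EMG stream for the whole trial
  n_emg <- n_base * emg_per_tick
  bp <- emg_carrier_fir(emg_cfg$carrier_band, fs)
  carrier <- vapply(seq_len(emg_cfg$n_channels), function(ch) {
    w <- as.numeric(signal::filter(bp, 1, stats::rnorm(n_emg)))
    w / max(stats::sd(w), 1e-12)
  }, numeric(n_emg))
  jitter <- if (emg_cfg$envelope_jitter > 0) {
    lp <- signal::butter(2, 2 / fs * 2, type = "low")
    vapply(1:4, function(k) {
      z <- as.numeric(signal::filter(lp, stats::rnorm(n_emg)))
      1 + emg_cfg$envelope_jitter * z / max(stats::sd(z), 1e-12)
    }, numeric(n_emg))
  } else matrix(1, n_emg, 4)

  # state
  q <- model$rest_joints
  hand <- arm_fk(model, q)$hand
  pron_int <- model$rest_pronation
  flex_prev <- q$flexion; pron_prev <- pron_int
  disp_flex <- q$flexion; disp_pron <- pron_int
  aim_corr <- c(0, 0, 0); pron_corr <- 0
  returning <- FALSE
  tgt_i <- tgt_i + 1L
  cur_tgt <- targets[[((tgt_i - 1L) %% length(targets)) + 1L]]
  state <- acquisition_state()
  R_h_prev <- NULL
  emg_buf <- matrix(0, n_emg, emg_cfg$n_channels)
  imu_t <- numeric(n_imu); imu_kin <- matrix(0, n_imu, 6)
  imu_i <- 0L
  p_hist <- matrix(NA_real_, 3, 3)     # last 3 sensor positions (m)
  frames <- NULL
  preds_f <- numeric(0); preds_p <- numeric(0)
  ticks <- vector("list", n_base %/% ctrl_every + 1)
  events <- list()
  events[[1]] <- data.frame(t = 0, type = "ONSET", target_id = tgt_i,
                            D = sqrt(sum((hand - cur_tgt$position)^2)))
  tick_i <- 0L

  for (i in seq_len(n_base)) {
    t <- i * base_dt
    # --- simulated user: intended motion toward the aim point
    aim <- if (returning) model$rest_hand else cur_tgt$position + aim_corr
    aim <- clip_reachable(aim, model)
    aim_pron <- if (returning) model$rest_pronation
                else min(160, max(0, cur_tgt$pronation + pron_corr))
    if (is.na(aim_pron)) aim_pron <- model$rest_pronation
    step <- (base_dt / tau_hand) * (aim - hand)
    spd <- sqrt(sum(step^2)) / base_dt
    if (spd > 30) step <- step * 30 / spd          # cap at 30 cm/s
    hand <- hand + step
    pron_int <- pron_int + (base_dt / tau_hand) * (aim_pron - pron_int)
    q <- arm_ik(model, clip_reachable(hand, model), pron_int)
    fk <- arm_fk(model, q)
    hand <- fk$hand

    # --- EMG synthesis for this base tick
    fv <- (q$flexion - flex_prev) / base_dt
    pv <- (pron_int - pron_prev) / base_dt
    flex_prev <- q$flexion; pron_prev <- pron_int
    env <- latent_activations(q$flexion, pron_int, fv, pv)
    rows <- ((i - 1) * emg_per_tick + 1):(i * emg_per_tick)
    env_j <- jitter[rows, , drop = FALSE] *
      matrix(env, emg_per_tick, 4, byrow = TRUE)
    amp <- pmax(env_j %*% t(emg_cfg$mixing_matrix) + emg_cfg$noise_floor, 0)
    emg_buf[rows, ] <- amp * carrier[rows, , drop = FALSE]

    # --- IMU sample at 50 Hz
    if (i %% imu_every == 0) {
      imu_i <- imu_i + 1L
      imu_t[imu_i] <- t
      R_h <- fk$r_humerus
      gy <- if (is.null(R_h_prev)) c(0, 0, 0)
            else angular_velocity(R_h_prev, R_h, imu_every * base_dt)
      R_h_prev <- R_h
      p_s <- as.vector(R_h %*% c(0, -model$L1 / 2, 0)) / 100
      p_hist <- rbind(p_hist[-1, , drop = FALSE], p_s)
      acc <- if (anyNA(p_hist)) {
        as.vector(t(R_h) %*% c(0, 9.81, 0))
      } else {
        dt2 <- (imu_every * base_dt)^2
        a_w <- (p_hist[3, ] - 2 * p_hist[2, ] + p_hist[1, ]) / dt2
        as.vector(t(R_h) %*% (a_w - c(0, -9.81, 0)))
      }
      imu_kin[imu_i, ] <- c(gy, acc)
    }

    # --- control tick every 50 ms
    if (i %% ctrl_every == 0) {
      n_emg_win <- round(0.15 * fs)
      have_hist <- i * emg_per_tick >= n_emg_win && imu_i >= 8
      if (mode == "oracle") {
        disp_flex <- q$flexion; disp_pron <- pron_int
      } else if (have_hist) {
        ew <- emg_buf[(i * emg_per_tick - n_emg_win + 1):(i * emg_per_tick),
                      , drop = FALSE]
        kw <- imu_kin[(imu_i - 7):imu_i, , drop = FALSE]
        fr <- c(condition_emg(ew, n_emg_win),
                condition_kinematics(kw, 8))
        frames <- rbind(frames, fr)
        if (nrow(frames) >= max_lag + 1) {
          x <- stack_row(frames, lags)
          preds_f <- c(preds_f, tdnn_predict(flex_model, x))
          preds_p <- c(preds_p, tdnn_predict(pron_model, x))
          nw <- min(10, length(preds_f))
          disp_flex <- smooth_last(preds_f, nw)
          disp_pron <- smooth_last(preds_p, nw)
        }
      }
      # displayed hand pose: intended humerus + displayed forearm
      q_disp <- q; q_disp$flexion <- disp_flex; q_disp$pronation <- disp_pron
      disp_hand <- arm_fk(model, q_disp)$hand

      if (!returning) {
        state <- update_acquisition(state, disp_hand, disp_pron, cur_tgt,
                                    rule, t)
        if (!is.na(state$event) && state$event != "ENTER")
          events[[length(events) + 1]] <- data.frame(
            t = t, type = state$event, target_id = tgt_i, D = NA_real_)
        if (state$acquired) {
          returning <- TRUE
          aim_corr <- c(0, 0, 0); pron_corr <- 0
        } else if (mode == "ann") {
          aim_corr <- aim_corr + corr_gain * (cur_tgt$position - disp_hand)
          aim_corr <- pmin(10, pmax(-10, aim_corr))
          if (!is.na(cur_tgt$pronation)) {
            pron_corr <- pron_corr +
              corr_gain * (cur_tgt$pronation - disp_pron)
            pron_corr <- min(45, max(-45, pron_corr))
          }
        }
      } else if (sqrt(sum((hand - model$rest_hand)^2)) < rule$pos_tol) {
        # back at rest: present the next target
        returning <- FALSE
        tgt_i <- tgt_i + 1L
        cur_tgt <- targets[[((tgt_i - 1L) %% length(targets)) + 1L]]
        state <- acquisition_state()
        events[[length(events) + 1]] <- data.frame(
          t = t, type = "ONSET", target_id = tgt_i,
          D = sqrt(sum((disp_hand - cur_tgt$position)^2)))
      }
      tick_i <- tick_i + 1L
      ticks[[tick_i]] <- data.frame(
        t = t, hx = disp_hand[1], hy = disp_hand[2], hz = disp_hand[3],
        hand_pron = disp_pron,
        truth_flexion = q$flexion, truth_pronation = pron_int,
        pred_flexion = disp_flex, pred_pronation = disp_pron,
        target_id = tgt_i, in_target = state$inside || state$acquired,
        segment = if (returning) "return" else "reach")
    }
  }
  log <- structure(list(ticks = do.call(rbind, ticks[seq_len(tick_i)]),
                        events = do.call(rbind, events),
                        trial_len = trial_len),
                   class = "trial_log")
  list(log = log, next_target_index = tgt_i)
}

clip_reachable <- function(p, model, margin = 1) {
  r <- sqrt(sum(p^2))
  rmax <- model$L1 + model$L2 - margin
  rmin <- abs(model$L1 - model$L2) + margin
  if (r > rmax) p * rmax / r else if (r < rmin) p * rmin / max(r, 1e-9) else p
}

# one delay-stacked input for the most recent frame; lag order matches
# stack_delays (ascending lags, current frame first)
stack_row <- function(frames, lags) {
  n <- nrow(frames)
  as.numeric(t(frames[n - lags, , drop = FALSE]))
}

smooth_last <- function(x, n, alpha = 0.2) {
  w <- x[(length(x) - n + 1):length(x)]
  mean(ema(w, alpha))
}
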