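#' Input/output signal conditioning
#'
#' The controller's conditioning chain. Every 50 ms a feature frame of 12
#' values is assembled: per EMG channel, the last 150 ms of raw samples are
#' detrended (window mean removed), rectified, passed through an exponential
#' moving average (EMA) filter and averaged; per gyroscope/accelerometer
#' channel, the last 150 ms of samples are EMA-filtered and averaged (no
#' detrend or rectification). Frames are delay-stacked over a configurable
#' tap set before entering the networks, and network outputs are smoothed
#' with the same EMA-then-mean operator over the last 0.5 s.
#'
#' The EMA smoothing constant is not stated by the protocol; the default is
#' `alpha = 0.2` (configurable per stream). Because the filter is
#' re-initialized at the first window sample and its output then averaged,
#' `alpha` must not be small relative to `2 / N`: a near-zero `alpha` leaves
#' the composite estimate dominated by the oldest samples of the window,
#' which multiplies the variance of the amplitude estimate several-fold.
#' Within the sane range (roughly 0.05-1) results are only mildly
#' `alpha`-sensitive.
#'
#' @name signals
NULL

#' Exponential moving average
#'
#' First-order recursive filter `y[i] = alpha * x[i] + (1 - alpha) *
#' y[i-1]`, initialized at the first sample.
#'
#' @param x numeric vector.
#' @param alpha smoothing constant in (0, 1].
#' @return filtered vector, same length.
#' @export
ema <- function(x, alpha = 0.2) {
  stopifnot(alpha > 0, alpha <= 1)
  n <- length(x)
  if (n == 0) return(x)
  # recursive filter with y[1] = x[1]
  y <- as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                                init = x[1]))
  y[1] <- x[1]
  y
}

#' Condition one 150 ms EMG window into one feature value per channel
#'
#' Detrend (subtract the window mean), rectify (absolute value), EMA-filter,
#' then average the filtered samples. The result is non-negative.
#'
#' @param window numeric matrix, 150 ms of 1000 Hz samples x channels (or a
#'   vector for one channel).
#' @param n_expected required window length in samples (no partial frames).
#' @param alpha EMA smoothing constant (0.2).
#' @return numeric vector, one value per channel, >= 0.
#' @export
condition_emg <- function(window, n_expected = 150, alpha = 0.2) {
  if (is.vector(window)) window <- matrix(window, ncol = 1)
  n <- nrow(window)
  if (n != n_expected)
    stop(sprintf("EMG window has %d samples; expected %d", n, n_expected))
  apply(window, 2, function(x) mean(ema(abs(x - mean(x)), alpha)))
}

#' Condition one 150 ms kinematic window into one feature value per channel
#'
#' EMA-filter then average; no detrending or rectification (gyroscope and
#' accelerometer values are signed physical quantities).
#'
#' @param window numeric matrix, samples x channels (8 samples at 50 Hz
#'   cover the 150 ms window with inclusive endpoints).
#' @param n_expected required window length in samples.
#' @param alpha EMA smoothing constant (0.2).
#' @return numeric vector, one value per channel.
#' @export
condition_kinematics <- function(window, n_expected = 8, alpha = 0.2) {
  if (is.vector(window)) window <- matrix(window, ncol = 1)
  n <- nrow(window)
  if (n != n_expected)
    stop(sprintf("kinematic window has %d samples; expected %d",
                 n, n_expected))
  apply(window, 2, function(x) mean(ema(x, alpha)))
}

#' Assemble 50 ms feature frames from raw sensor streams
#'
#' Emits one 12-value frame (6 EMG + 3 gyro + 3 accel features) on a strict
#' 50 ms grid, each computed from the most recent 150 ms of raw data, plus
#' the ground-truth output angles at the frame time (the network training
#' targets). Frames start once a full 150 ms of history exists.
#'
#' @param streams a `sensor_streams` object.
#' @param frame_period frame spacing, s (0.05).
#' @param emg_window_s EMG conditioning history, s (0.15).
#' @param kin_window_n kinematic window length in samples (8).
#' @return object of class `feature_frames`: `t` (frame times), `features`
#'   (T x 12 matrix), `truth` (T x 2: flexion, pronation),
#'   `target_id`, `segment` carried from the stream.
#' @export
feature_frames <- function(streams, frame_period = 0.05,
                           emg_window_s = 0.15, kin_window_n = 8) {
  fs <- streams$emg_cfg$sample_rate
  n_emg_win <- round(emg_window_s * fs)
  t_end <- min(max(streams$t_emg), max(streams$t_imu))
  t_start_min <- max(streams$t_emg[n_emg_win],
                     streams$t_imu[kin_window_n])
  first_k <- ceiling(round(t_start_min / frame_period, 9))
  tt <- seq(first_k, floor(round(t_end / frame_period, 9))) * frame_period
  kin <- cbind(streams$gyro, streams$accel)
  feats <- matrix(NA_real_, length(tt), 12)
  truth <- matrix(NA_real_, length(tt), 2)
  tid <- integer(length(tt)); segm <- character(length(tt))
  for (j in seq_along(tt)) {
    t <- tt[j]
    ie <- findInterval(t + 1e-9, streams$t_emg)
    ik <- findInterval(t + 1e-9, streams$t_imu)
    ew <- streams$emg[(ie - n_emg_win + 1):ie, , drop = FALSE]
    kw <- kin[(ik - kin_window_n + 1):ik, , drop = FALSE]
    feats[j, ] <- c(condition_emg(ew, n_emg_win),
                    condition_kinematics(kw, kin_window_n))
    truth[j, ] <- c(streams$truth$flexion[ik], streams$truth$pronation[ik])
    tid[j] <- streams$truth$target_id[ik]
    segm[j] <- streams$truth$segment[ik]
  }
  colnames(feats) <- c(paste0("emg", 1:6),
                       paste0("gyro_", c("x", "y", "z")),
                       paste0("accel_", c("x", "y", "z")))
  colnames(truth) <- c("flexion", "pronation")
  structure(list(t = tt, features = feats, truth = truth,
                 target_id = tid, segment = segm),
            class = "feature_frames")
}

#' @export
print.feature_frames <- function(x, ...) {
  cat(sprintf("<feature_frames> %d frames x %d features, %.2f-%.2f s\n",
              length(x$t), ncol(x$features), min(x$t), max(x$t)))
  invisible(x)
}

#' Delay-stack a feature-frame stream
#'
#' For each emission time t, concatenates the frames at `t - lag * 50 ms`
#' for each lag in the tap set; the stream is shortened by `max(lags)`
#' frames. With the default taps `c(0, 1, 2, 3)` (the current frame plus
#' three input time delays) each 12-feature frame becomes a 48-value input
#' vector.
#'
#' @param x T x p feature matrix (rows = frames, time-ordered).
#' @param lags sorted unique non-negative integer tick offsets.
#' @return (T - max(lags)) x (p * length(lags)) matrix; row i corresponds to
#'   input-frame row `i + max(lags)`.
#' @export
stack_delays <- function(x, lags = c(0, 1, 2, 3)) {
  stopifnot(all(lags >= 0), !is.unsorted(lags), !anyDuplicated(lags))
  x <- as.matrix(x)
  m <- max(lags)
  n_out <- nrow(x) - m
  if (n_out <= 0) stop("stream shorter than the largest delay")
  cn <- if (is.null(colnames(x))) paste0("f", seq_len(ncol(x)))
        else colnames(x)
  do.call(cbind, lapply(lags, function(l) {
    xi <- x[(m - l + 1):(nrow(x) - l), , drop = FALSE]
    colnames(xi) <- paste0(cn, "_lag", l)
    xi
  }))
}

#' Smooth a predicted-angle stream (output post-processing)
#'
#' At each 50 ms tick: EMA-filter the predictions from the last 0.5 s
#' (10 ticks) and average them. During warm-up the available history is
#' used. Constant input is reproduced exactly.
#'
#' @param pred numeric vector of per-tick predictions.
#' @param window_ticks smoothing history, ticks (10 = 0.5 s at 50 ms).
#' @param alpha EMA constant (0.2).
#' @return smoothed vector, same length.
#' @export
smooth_output <- function(pred, window_ticks = 10, alpha = 0.2) {
  n <- length(pred)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- pred[max(1, i - window_ticks + 1):i]
    out[i] <- mean(ema(w, alpha))
  }
  out
}
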