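#' Fitts-law movement metrics
#'
#' The evaluation suite computed from `trial_log` objects: index of
#' difficulty `ID = log2(D/W + 1)` (D = distance from the hand position at
#' target onset to the target, W = target width), throughput (ID divided by
#' the movement time from target onset to acquisition), overshoot (count of
#' premature target exits divided by targets presented), path efficiency
#' (straight-line distance over path arc length), per-acquisition time to
#' target, per-trial time remaining after the last acquisition, and the
#' online prediction RMSE.
#'
#' @name metrics
NULL

#' Index of difficulty
#'
#' @param D distance from the initial hand position to the target, cm.
#' @param W target size, cm.
#' @return bits.
#' @export
index_of_difficulty <- function(D, W) {
  if (any(W <= 0)) stop("W must be positive")
  stopifnot(all(D >= 0))
  log2(D / W + 1)
}

# per-acquired-target table: onset, acquisition, D, ID, movement time
acquired_table <- function(log, W = 10) {
  ev <- log$events
  on <- ev[ev$type == "ONSET", ]
  ac <- ev[ev$type == "ACQUIRED", ]
  if (nrow(ac) == 0) return(NULL)
  idx <- match(ac$target_id, on$target_id)
  data.frame(target_id = ac$target_id,
             t_onset = on$t[idx], t_acq = ac$t,
             D = on$D[idx],
             ID = index_of_difficulty(on$D[idx], W),
             movement_time = ac$t - on$t[idx])
}

#' Throughput per acquired target
#'
#' Movement time runs from target onset to the `ACQUIRED` event (the 0.5 s
#' hold included).
#'
#' @param logs a `trial_log` or list of them.
#' @param W target size, cm.
#' @return list: `per_target` data.frame (ID bits, movement time s,
#'   throughput bits/s), `mean`, `median` (bits/s). Empty logs give an
#'   empty table.
#' @export
throughput <- function(logs, W = 10) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  tabs <- Filter(Negate(is.null), lapply(logs, acquired_table, W = W))
  if (length(tabs) == 0)
    return(list(per_target = data.frame(), mean = NA_real_,
                median = NA_real_))
  tab <- do.call(rbind, tabs)
  tab$throughput <- tab$ID / tab$movement_time
  list(per_target = tab, mean = mean(tab$throughput),
       median = stats::median(tab$throughput))
}

#' Overshoot rate
#'
#' `EXIT` events (entering then leaving the target before the 0.5 s hold)
#' divided by the number of targets presented; a ratio of counts, not
#' clamped.
#'
#' @param logs a `trial_log` or list of them.
#' @return fraction.
#' @export
overshoot <- function(logs) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  ev <- do.call(rbind, lapply(logs, `[[`, "events"))
  n_presented <- sum(ev$type == "ONSET")
  if (n_presented == 0) stop("no targets presented")
  sum(ev$type == "EXIT") / n_presented
}

#' Path efficiency per acquired target
#'
#' Straight-line distance from the hand position at target onset to the
#' target, divided by the arc length actually travelled (polyline over
#' ticks) between onset and acquisition. Bounded by 1 for any path that
#' ends at the target.
#'
#' @param logs a `trial_log` or list of them.
#' @return list: `per_target` values, `mean`, `median`.
#' @export
path_efficiency <- function(logs) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  vals <- unlist(lapply(logs, function(log) {
    tab <- acquired_table(log)
    if (is.null(tab)) return(numeric(0))
    vapply(seq_len(nrow(tab)), function(i) {
      sel <- log$ticks$t >= tab$t_onset[i] - 1e-9 &
        log$ticks$t <= tab$t_acq[i] + 1e-9
      P <- as.matrix(log$ticks[sel, c("hx", "hy", "hz")])
      if (nrow(P) < 2) return(NA_real_)
      arc <- sum(sqrt(rowSums(diff(P)^2)))
      if (arc <= 0) {
        warning("zero path length for target ", tab$target_id[i])
        return(NA_real_)
      }
      sqrt(sum((P[nrow(P), ] - P[1, ])^2)) / arc
    }, numeric(1))
  }))
  vals <- vals[!is.na(vals)]
  list(per_target = vals,
       mean = if (length(vals)) mean(vals) else NA_real_,
       median = if (length(vals)) stats::median(vals) else NA_real_)
}

#' Time to target and time remaining per trial
#'
#' Per acquisition, the elapsed time since that target's onset; per trial,
#' the residual trial time after the last acquisition (the full trial
#' length when nothing was acquired).
#'
#' @param logs a `trial_log` or list of them.
#' @return list: `times_to_target` (s), `time_remaining` (s, one per
#'   trial), and their medians/IQRs.
#' @export
time_summaries <- function(logs) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  ttt <- unlist(lapply(logs, function(log) {
    tab <- acquired_table(log)
    if (is.null(tab)) numeric(0) else tab$movement_time
  }))
  rem <- vapply(logs, function(log) {
    ac <- log$events[log$events$type == "ACQUIRED", ]
    t0 <- min(log$ticks$t)
    if (nrow(ac) == 0) log$trial_len
    else log$trial_len - (max(ac$t) - t0)
  }, numeric(1))
  list(times_to_target = ttt, time_remaining = rem,
       median_time_to_target = stats::median(ttt),
       iqr_time_to_target = unname(stats::quantile(ttt, c(0.25, 0.75),
                                                   na.rm = TRUE)),
       median_time_remaining = stats::median(rem))
}

#' Online prediction RMSE
#'
#' RMSE between the ground-truth (measured) and network-predicted angles
#' over all ticks of all trials, per degree of freedom.
#'
#' @param logs a `trial_log` or list of them (from the closed-loop phase).
#' @return named vector: `flexion`, `pronation` (degrees).
#' @export
online_rmse <- function(logs) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  ticks <- do.call(rbind, lapply(logs, `[[`, "ticks"))
  if (all(is.na(ticks$pred_flexion)))
    stop("logs carry no predictions (not a closed-loop phase?)")
  c(flexion = sqrt(mean((ticks$truth_flexion - ticks$pred_flexion)^2,
                        na.rm = TRUE)),
    pronation = sqrt(mean((ticks$truth_pronation - ticks$pred_pronation)^2,
                          na.rm = TRUE)))
}

#' Full metrics report for a set of trial logs
#'
#' @param logs list of `trial_log`s.
#' @param W target size, cm.
#' @param online include online RMSE (closed-loop logs only).
#' @return nested list suitable for JSON serialization.
#' @export
metrics_report <- function(logs, W = 10, online = FALSE) {
  tp <- throughput(logs, W)
  pe <- path_efficiency(logs)
  ts <- time_summaries(logs)
  out <- list(
    n_presented = sum(vapply(logs, function(l)
      sum(l$events$type == "ONSET"), numeric(1))),
    n_acquired = sum(vapply(logs, function(l)
      sum(l$events$type == "ACQUIRED"), numeric(1))),
    throughput_mean = tp$mean, throughput_median = tp$median,
    overshoot = overshoot(logs),
    path_efficiency_mean = pe$mean, path_efficiency_median = pe$median,
    median_time_to_target = ts$median_time_to_target,
    median_time_remaining = ts$median_time_remaining)
  if (online) {
    rmse <- online_rmse(logs)
    out$online_rmse_flexion <- unname(rmse["flexion"])
    out$online_rmse_pronation <- unname(rmse["pronation"])
  }
  out
}
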