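test_that("index of difficulty follows log2(D/W + 1)", {
  expect_equal(index_of_difficulty(0, 10), 0)
  expect_equal(index_of_difficulty(10, 10), 1)
  expect_equal(index_of_difficulty(30, 10), 2)
  expect_error(index_of_difficulty(10, 0), "positive")
})

test_that("throughput divides ID by movement time, per acquired target", {
  log <- straight_log(D = 30, mt = 4)      # ID = 2 bits in 4 s
  tp <- throughput(log)
  expect_equal(tp$per_target$throughput, 0.5)
  expect_equal(tp$mean, 0.5)

  # doubling movement times halves throughput
  log2x <- straight_log(D = 30, mt = 8)
  expect_equal(throughput(log2x)$per_target$throughput, 0.25)

  # hand-built two-target fixture against hand-computed values
  ev <- data.frame(t = c(0, 5, 10, 16),
                   type = c("ONSET", "ACQUIRED", "ONSET", "ACQUIRED"),
                   target_id = c(1L, 1L, 2L, 2L),
                   D = c(20, NA, 10, NA))
  tk <- data.frame(t = seq(0, 20, by = 0.05), hx = 0, hy = 0, hz = -45,
                   hand_pron = 90, truth_flexion = 0, truth_pronation = 90,
                   pred_flexion = 0, pred_pronation = 90, target_id = 1L,
                   in_target = FALSE, segment = "reach")
  log <- make_log(tk, ev, 30)
  tp <- throughput(log)
  expect_equal(tp$per_target$throughput,
               c(log2(20 / 10 + 1) / 5, log2(10 / 10 + 1) / 6))
  expect_equal(tp$median, stats::median(tp$per_target$throughput))

  # no acquisitions: empty result, not an error
  ev0 <- data.frame(t = 0, type = "ONSET", target_id = 1L, D = 20)
  expect_equal(nrow(throughput(make_log(tk, ev0, 30))$per_target), 0)
})

test_that("overshoot counts premature exits over targets presented", {
  log <- straight_log()
  expect_equal(overshoot(log), 0)

  ev <- do.call(rbind, c(
    lapply(1:60, function(i) data.frame(t = i, type = "ONSET",
                                        target_id = i, D = 10)),
    lapply(1:3, function(i) data.frame(t = 60 + i, type = "EXIT",
                                       target_id = i, D = NA))))
  log <- make_log(straight_log()$ticks, ev, 30)
  expect_equal(overshoot(log), 0.05)
})

test_that("path efficiency is straight-line over arc length", {
  expect_equal(path_efficiency(straight_log())$mean, 1, tolerance = 1e-6)

  # two legs of a right isosceles triangle: efficiency 1/sqrt(2)
  tt <- seq(0, 2, by = 0.05)
  leg1 <- tt[tt <= 1]; leg2 <- tt[tt > 1]
  tk <- data.frame(t = tt,
                   hx = c(leg1 * 10, rep(10, length(leg2))),
                   hy = c(rep(0, length(leg1)), (leg2 - 1) * 10),
                   hz = -45, hand_pron = 90, truth_flexion = 0,
                   truth_pronation = 90, pred_flexion = 0,
                   pred_pronation = 90, target_id = 1L, in_target = FALSE,
                   segment = "reach")
  ev <- data.frame(t = c(0, 2), type = c("ONSET", "ACQUIRED"),
                   target_id = 1L, D = c(sqrt(200), NA))
  pe <- path_efficiency(make_log(tk, ev, 30))
  expect_equal(pe$mean, 1 / sqrt(2), tolerance = 1e-9)

  # random walk against the independent arc-length oracle
  set.seed(13)
  P <- apply(matrix(rnorm(3 * 41), 41, 3), 2, cumsum)
  tk <- data.frame(t = seq(0, 2, by = 0.05), hx = P[, 1], hy = P[, 2],
                   hz = P[, 3], hand_pron = 90, truth_flexion = 0,
                   truth_pronation = 90, pred_flexion = 0,
                   pred_pronation = 90, target_id = 1L, in_target = FALSE,
                   segment = "reach")
  pe <- path_efficiency(make_log(tk, ev, 30))
  expect_equal(pe$mean,
               sqrt(sum((P[41, ] - P[1, ])^2)) / oracle_arc_length(P),
               tolerance = 1e-9)
})

test_that("time summaries report time-to-target and time remaining", {
  log <- straight_log(mt = 4, trial_len = 30)
  ts <- time_summaries(log)
  expect_equal(ts$times_to_target, 4)
  expect_equal(ts$time_remaining, 26)

  # no acquisitions: remaining is the full trial length
  ev0 <- data.frame(t = 0, type = "ONSET", target_id = 1L, D = 20)
  ts <- time_summaries(make_log(straight_log()$ticks, ev0, 30))
  expect_equal(ts$time_remaining, 30)
  expect_length(ts$times_to_target, 0)

  # multi-event fixture vs hand computation
  ev <- data.frame(t = c(0, 5, 6, 13.5),
                   type = c("ONSET", "ACQUIRED", "ONSET", "ACQUIRED"),
                   target_id = c(1L, 1L, 2L, 2L), D = c(20, NA, 15, NA))
  ts <- time_summaries(make_log(straight_log()$ticks, ev, 30))
  expect_equal(ts$times_to_target, c(5, 7.5))
  expect_equal(ts$time_remaining, 30 - 13.5)
})

test_that("online RMSE matches the two-line oracle", {
  log <- straight_log()
  expect_equal(unname(online_rmse(log)), c(0, 0))

  log$ticks$pred_flexion <- log$ticks$truth_flexion + 5
  expect_equal(unname(online_rmse(log)["flexion"]), 5)

  set.seed(17)
  log$ticks$pred_flexion <- log$ticks$truth_flexion + rnorm(nrow(log$ticks))
  log$ticks$pred_pronation <- log$ticks$truth_pronation +
    rnorm(nrow(log$ticks))
  r <- online_rmse(log)
  expect_equal(unname(r["flexion"]),
               oracle_rmse(log$ticks$pred_flexion, log$ticks$truth_flexion))
  expect_equal(unname(r["pronation"]),
               oracle_rmse(log$ticks$pred_pronation,
                           log$ticks$truth_pronation))

  log$ticks$pred_flexion <- NA_real_
  log$ticks$pred_pronation <- NA_real_
  expect_error(online_rmse(log), "predictions")
})

test_that("metric invariants hold on random logs", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    P <- apply(matrix(rnorm(3 * n, sd = 3), n, 3), 2, cumsum)
    tk <- data.frame(t = seq_len(n) * 0.05, hx = P[, 1], hy = P[, 2],
                     hz = P[, 3], hand_pron = 90, truth_flexion = 0,
                     truth_pronation = 90, pred_flexion = 0,
                     pred_pronation = 90, target_id = 1L,
                     in_target = FALSE, segment = "reach")
    n_exit <- sample(0:3, 1)
    ev <- rbind(
      data.frame(t = 0.05, type = "ONSET", target_id = 1L,
                 D = sqrt(sum((P[n, ] - P[1, ])^2))),
      if (n_exit > 0) data.frame(t = 0.1 + seq_len(n_exit) * 0.05,
                                 type = "EXIT", target_id = 1L, D = NA),
      data.frame(t = n * 0.05, type = "ACQUIRED", target_id = 1L, D = NA))
    log <- make_log(tk, ev, 30)
    pe <- path_efficiency(log)$mean
    expect_lte(pe, 1 + 1e-12)
    expect_gt(pe, 0)
    expect_gte(overshoot(log), 0)
  }
})

test_that("event counts are additive over concatenated logs and ID is translation invariant", {
  logA <- straight_log(D = 30, mt = 4)
  logB <- straight_log(D = 10, mt = 2)
  logB$events$target_id <- 2L; logB$ticks$target_id <- 2L
  both <- list(logA, logB)
  expect_equal(nrow(throughput(both)$per_target),
               nrow(throughput(logA)$per_target) +
                 nrow(throughput(logB)$per_target))
  # translating the whole workspace leaves D (hence ID, throughput) alone
  logT <- logA
  logT$ticks$hx <- logT$ticks$hx + 100
  expect_equal(throughput(logT)$mean, throughput(logA)$mean)
})
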