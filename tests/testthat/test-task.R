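test_that("the preset protocol is a 4x4x2 grid at two orientations", {
  tg <- preset_training_targets()
  expect_length(tg, 64)
  pron <- vapply(tg, `[[`, numeric(1), "pronation")
  expect_true(all(pron[1:32] == 30))
  expect_true(all(pron[33:64] == 90))
  pos <- t(vapply(tg, `[[`, numeric(3), "position"))
  expect_true(all(pos[, 1] >= -10 & pos[, 1] <= 20))
  expect_true(all(pos[, 2] >= -10 & pos[, 2] <= 20))
  expect_true(all(pos[, 3] >= -50 & pos[, 3] <= -40))
  expect_equal(nrow(unique(pos)), 32)    # 32 distinct locations
  expect_identical(pos[1:32, ], pos[33:64, ])
})

test_that("random test targets are seeded draws from the shrunk workspace", {
  t1 <- random_test_targets(50, seed = 5)
  t2 <- random_test_targets(50, seed = 5)
  expect_identical(t1, t2)

  pos <- t(vapply(t1, `[[`, numeric(3), "position"))
  expect_true(all(pos[, 1] >= -8 & pos[, 1] <= 18))
  expect_true(all(pos[, 2] >= -8 & pos[, 2] <= 18))
  expect_true(all(pos[, 3] >= -48 & pos[, 3] <= -42))

  # orientation frequencies ~ binomial(n, 1/2): 99% CI for n = 1000
  tn <- random_test_targets(1000, seed = 6)
  n30 <- sum(vapply(tn, `[[`, numeric(1), "pronation") == 30)
  expect_true(n30 > 500 - 2.58 * sqrt(250) & n30 < 500 + 2.58 * sqrt(250))

  expect_error(random_test_targets(5, seed = 1, shrink_margin = 10),
               "collapses")
})

test_that("the acquisition machine fires ENTER/EXIT/ACQUIRED correctly", {
  tg <- reach_target(c(0, 0, -45), 90)
  rule <- acquisition_rule()
  tick <- 0.05

  # never inside: no events
  st <- acquisition_state()
  for (k in 1:40) {
    st <- update_acquisition(st, c(0, 0, -30), 90, tg, rule, k * tick)
    expect_true(is.na(st$event) || st$event == "")
  }
  expect_false(st$acquired)

  # inside continuously: ACQUIRED exactly at entry + 0.5 s
  st <- acquisition_state()
  events <- character(0)
  for (k in 1:40) {
    st <- update_acquisition(st, c(0, 0, -44), 90, tg, rule, k * tick)
    if (!is.na(st$event)) events <- c(events, sprintf("%s@%.2f", st$event,
                                                      k * tick))
  }
  expect_equal(events, c("ENTER@0.05", "ACQUIRED@0.55"))

  # inside 0.3 s, out, back inside 0.5 s: one EXIT then one ACQUIRED
  st <- acquisition_state()
  trace <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 11))
  events <- character(0)
  for (k in seq_along(trace)) {
    p <- if (trace[k]) c(0, 0, -44) else c(0, 0, -30)
    st <- update_acquisition(st, p, 90, tg, rule, k * tick)
    if (!is.na(st$event)) events <- c(events, st$event)
  }
  expect_equal(events, c("ENTER", "EXIT", "ENTER", "ACQUIRED"))

  # orientation gate: wrong pronation blocks entry; NA pronation skips it
  st <- update_acquisition(acquisition_state(), c(0, 0, -44), 150, tg,
                           rule, 0.05)
  expect_false(st$inside)
  tg_na <- reach_target(c(0, 0, -45), NA)
  st <- update_acquisition(acquisition_state(), c(0, 0, -44), 150, tg_na,
                           rule, 0.05)
  expect_true(st$inside)
})

test_that("ground-truth control acquires every presented target", {
  st <- small_session(6, seed = 10)
  tg <- preset_training_targets()[1:6]
  log <- run_imu_phase(st, tg)
  ev <- log$events
  expect_equal(sum(ev$type == "ONSET"), 6)
  expect_equal(sum(ev$type == "ACQUIRED"), 6)
  expect_equal(sum(ev$type == "EXIT"), 0)

  # no acquisition without a preceding continuous 0.5 s inside
  for (id in unique(ev$target_id[ev$type == "ACQUIRED"])) {
    t_acq <- ev$t[ev$type == "ACQUIRED" & ev$target_id == id]
    sel <- log$ticks$target_id == id & log$ticks$t > t_acq - 0.5 - 1e-9 &
      log$ticks$t <= t_acq + 1e-9
    expect_true(all(log$ticks$in_target[sel]))
  }

  # events reconstructible from tick flags: each acquired target has an
  # unbroken in-target run of at least the hold time
  runs <- rle(log$ticks$in_target & log$ticks$segment != "return")
  expect_gte(max(runs$lengths[runs$values]), 25)
})

test_that("the closed-loop engine with oracle predictions tracks truth exactly", {
  m <- arm_model()
  tgt <- random_test_targets(20, seed = 20)
  logs <- run_ann_phase(m, targets = tgt, n_trials = 1, trial_len = 20,
                        mode = "oracle", seed = 21)
  expect_length(logs, 1)
  lg <- logs[[1]]
  expect_equal(nrow(lg$ticks), 20 / 0.05)
  expect_equal(unname(online_rmse(lg)), c(0, 0))
  expect_gte(sum(lg$events$type == "ACQUIRED"), 1)
  expect_true(all(diff(lg$ticks$t) > 0))
})

test_that("constant-output (broken) networks cannot complete the task", {
  m <- arm_model()
  broken <- structure(list(W1 = matrix(0, 6, 48), b1 = rep(0, 6),
                           W2 = rep(0, 6), b2 = 10,
                           input_mean = rep(0, 48), input_sd = rep(1, 48),
                           hidden_units = 6L, lags = c(0, 1, 2, 3),
                           target_name = "flexion"),
                      class = "tdnn_model")
  broken_p <- broken; broken_p$b2 <- 90; broken_p$target_name <- "pronation"
  # a target needing a large elbow flexion change and 30 deg pronation:
  # a frozen forearm leaves the hand shell > 5 cm away and 60 deg off
  tgt <- lapply(1:10, function(i) reach_target(c(15, 15, -48), 30))
  logs <- run_ann_phase(m, broken, broken_p, tgt, n_trials = 2,
                        trial_len = 20, mode = "ann", seed = 22)
  ev <- do.call(rbind, lapply(logs, `[[`, "events"))
  expect_equal(sum(ev$type == "ACQUIRED"), 0)
})
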