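test_that("inverse kinematics places the hand exactly where asked", {
  m <- arm_model()
  set.seed(2)
  for (i in 1:200) {
    p <- c(runif(1, -10, 20), runif(1, -10, 20), runif(1, -50, -40))
    pr <- sample(c(30, 90), 1)
    q <- arm_ik(m, p, pr)
    fk <- arm_fk(m, q)
    expect_lt(sqrt(sum((fk$hand - p)^2)), 0.1)
    # ground-truth angles recovered by the kinematics module match exactly
    z <- elbow_forearm_angles(fk$r_humerus, fk$r_forearm)
    expect_equal(z$elbow_flexion, q$flexion, tolerance = 1e-6)
    expect_equal(z$pronation, q$pronation, tolerance = 1e-6)
  }
  expect_error(arm_ik(m, c(0, 0, -100), 90), "out of reach")
})

test_that("minimum-jerk reaches are symmetric with peak speed 1.875 d/T", {
  m <- arm_model()
  tgt <- list(position = c(10, 5, -45), pronation = 30)

  # start == target: constant trajectory
  q0 <- arm_ik(m, tgt$position, tgt$pronation)
  tr <- plan_reach(m, q0, tgt, duration = 2)
  expect_lt(max(abs(tr$hx - tgt$position[1])), 1e-9)
  expect_lt(diff(range(tr$flexion)), 1e-9)

  # temporal midpoint is the spatial midpoint
  tr <- plan_reach(m, m$rest_joints, tgt, duration = 4, tick = 0.02)
  p0 <- arm_fk(m, m$rest_joints)$hand
  mid <- tr[abs(tr$t - 2) < 1e-9, c("hx", "hy", "hz")]
  expect_equal(unlist(mid, use.names = FALSE), (p0 + tgt$position) / 2,
               tolerance = 1e-9)

  # peak hand speed (numeric differentiation) = 1.875 * distance / duration
  P <- as.matrix(tr[, c("hx", "hy", "hz")])
  v <- sqrt(rowSums(diff(P)^2)) / 0.02
  d <- sqrt(sum((tgt$position - p0)^2))
  expect_equal(max(v), 1.875 * d / 4, tolerance = 0.01)
})

test_that("EMG synthesis is zero without drive and linear in the envelope", {
  cfg <- emg_synth_config(noise_floor = 0, envelope_jitter = 0)
  env0 <- matrix(0, 500, 4)
  set.seed(1)
  expect_equal(max(abs(synthesize_emg(cfg = cfg, envelopes = env0))), 0)

  env1 <- env0; env1[, 1] <- 0.5
  set.seed(1); e1 <- synthesize_emg(cfg = cfg, envelopes = env1)
  set.seed(1); e2 <- synthesize_emg(cfg = cfg, envelopes = 2 * env1)
  expect_equal(mean(abs(e2[, 1])), 2 * mean(abs(e1[, 1])),
               tolerance = 1e-12)
})

test_that("rectified-mean EMG amplitude tracks its generating envelope", {
  # ~60 s synthetic stream under the default configuration
  m <- arm_model()
  st <- run_protocol_session(m, preset_training_targets()[1:7], seed = 3)
  fr <- feature_frames(st)
  # reconstruct the generating per-channel amplitude at the frame times
  fs <- st$emg_cfg$sample_rate
  flex <- approx(st$t_imu, st$truth$flexion, st$t_emg, rule = 2)$y
  pron <- approx(st$t_imu, st$truth$pronation, st$t_emg, rule = 2)$y
  env <- latent_activations(flex, pron, c(0, diff(flex)) * fs,
                            c(0, diff(pron)) * fs)
  amp <- env %*% t(st$emg_cfg$mixing_matrix) + st$emg_cfg$noise_floor
  idx <- findInterval(fr$t + 1e-9, st$t_emg)
  r2 <- vapply(1:6, function(ch) {
    tamp <- vapply(idx, function(i) mean(amp[(i - 149):i, ch]), numeric(1))
    cor(fr$features[, ch], tamp)^2
  }, numeric(1))
  expect_gte(max(r2), 0.9)     # the strongly modulated channel
  expect_true(all(r2 > 0.5))   # every channel is predictable from its drive
})

test_that("protocol sessions have consistent clocks and reproducible streams", {
  st <- small_session(3, seed = 8)
  # durations: n * (reach + hold + return), within one tick
  expect_equal(max(st$t_imu), 3 * (4 + 0.5 + 4), tolerance = 0.02 + 1e-9)
  # 20 EMG samples per IMU tick
  expect_equal(length(st$t_emg) - 1, (length(st$t_imu) - 1) * 20)
  expect_false(anyNA(st$emg)); expect_false(anyNA(st$gyro))
  expect_false(anyNA(st$accel))

  st2 <- small_session(3, seed = 8)
  expect_identical(st$emg, st2$emg)
  expect_identical(st$gyro, st2$gyro)

  st3 <- small_session(3, seed = 9)
  expect_false(identical(st$emg, st3$emg))

  # empty protocol: empty streams
  st0 <- run_protocol_session(arm_model(), list())
  expect_equal(length(st0$t_imu), 0)
  expect_equal(nrow(st0$emg), 0)
})

test_that("synthesized IMU channels agree with the kinematic oracles", {
  st <- small_session(2, seed = 4)
  tr <- st$truth
  n <- nrow(tr)
  # re-derive the humerus angular velocity from consecutive orientations
  i <- sample(2:n, 25)
  for (k in i) {
    R0 <- compose_thoracohumeral(tr$plane[k - 1], tr$elevation[k - 1],
                                 tr$axial[k - 1])
    R1 <- compose_thoracohumeral(tr$plane[k], tr$elevation[k], tr$axial[k])
    expect_equal(unname(st$gyro[k, ]),
                 angular_velocity(R0, R1, 0.02), tolerance = 1e-9)
  }
  # accelerometer magnitude ~ gravity when still (first sample, at rest)
  expect_equal(sqrt(sum(st$accel[1, ]^2)), 9.81, tolerance = 0.05)
})

test_that("session CSV round-trip preserves the streams", {
  st <- small_session(2, seed = 6)
  d <- tempfile("sess")
  write_session(st, d)
  expect_true(all(file.exists(file.path(d, c("emg.csv", "imu.csv",
                                             "session.json")))))
  st2 <- read_session(d)
  expect_equal(unname(st2$emg), unname(st$emg), tolerance = 1e-12)
  expect_equal(unname(st2$gyro), unname(st$gyro), tolerance = 1e-12)
  expect_equal(st2$truth$flexion, st$truth$flexion, tolerance = 1e-12)
  expect_equal(st2$emg_cfg$mixing_matrix, st$emg_cfg$mixing_matrix)

  # same seed, written twice: identical files
  d2 <- tempfile("sess")
  write_session(small_session(2, seed = 6), d2)
  expect_identical(readLines(file.path(d, "emg.csv")),
                   readLines(file.path(d2, "emg.csv")))
})
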