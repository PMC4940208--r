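# Independent oracle implementations used to check the package's operators.
# These are deliberately naive (sample-by-sample loops, direct formulas) and
# never call the functions they verify.

oracle_ema <- function(x, alpha) {
  y <- numeric(length(x))
  y[1] <- x[1]
  for (i in seq_along(x)[-1]) y[i] <- alpha * x[i] + (1 - alpha) * y[i - 1]
  y
}

oracle_rmse <- function(a, b) sqrt(sum((a - b)^2) / length(a))

# random rotation from a uniform quaternion (independent of the package's
# axis-angle constructor)
oracle_random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

oracle_arc_length <- function(P) {
  s <- 0
  for (i in 2:nrow(P)) s <- s + sqrt(sum((P[i, ] - P[i - 1, ])^2))
  s
}

# hand-built trial log for metric fixtures
make_log <- function(ticks, events, trial_len) {
  structure(list(ticks = ticks, events = events, trial_len = trial_len),
            class = "trial_log")
}

# straight-line log: one target acquired after `mt` seconds at distance D
straight_log <- function(D = 20, mt = 4, trial_len = 30, tick = 0.05) {
  tt <- seq(0, trial_len, by = tick)
  frac <- pmin(1, tt / mt)
  ticks <- data.frame(t = tt, hx = frac * D, hy = 0, hz = -45,
                      hand_pron = 90, truth_flexion = 45,
                      truth_pronation = 90, pred_flexion = 45,
                      pred_pronation = 90, target_id = 1L,
                      in_target = FALSE, segment = "reach")
  events <- data.frame(t = c(0, mt), type = c("ONSET", "ACQUIRED"),
                       target_id = 1L, D = c(D, NA))
  make_log(ticks, events, trial_len)
}

# a tiny deterministic arm/session shared by several tests
small_session <- function(n_targets = 4, seed = 11, ...) {
  m <- arm_model()
  tg <- preset_training_targets()[seq_len(n_targets)]
  run_protocol_session(m, tg, seed = seed, ...)
}
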