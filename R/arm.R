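#' Synthetic subject arm model
#'
#' A two-segment right arm in the shoulder-centred frame (x lateral,
#' y superior, z posterior; targets sit anteriorly at negative z). At the
#' reference pose (all rotations identity) both segments hang along -y. The
#' humerus orientation `R_h` is relative to the thorax; the forearm
#' orientation is `R_h %*% Rx(flexion) %*% Ry(pronation)`. Positions are in
#' centimetres.
#'
#' Default segment lengths (upper arm 33 cm, shoulder-to-hand-centre forearm
#' 27 cm) give a 60 cm reach, covering the task workspace (farthest corner
#' 57.4 cm) with margin, as for a tall adult reaching with the hand segment
#' included.
#'
#' @param upper_arm_length,forearm_length segment lengths, cm.
#' @param shoulder_origin position of the shoulder in the world frame, cm.
#' @param rest_hand hand-centre position of the relaxed (lap-like) posture,
#'   cm, shoulder frame.
#' @param rest_pronation pronation at rest, deg (90 = neutral).
#' @return object of class `arm_model`.
#' @export
arm_model <- function(upper_arm_length = 33, forearm_length = 27,
                      shoulder_origin = c(0, 0, 0),
                      rest_hand = c(0, -25, -15), rest_pronation = 90) {
  stopifnot(upper_arm_length > 0, forearm_length > 0)
  m <- structure(list(L1 = upper_arm_length, L2 = forearm_length,
                      shoulder = shoulder_origin,
                      rest_hand = rest_hand,
                      rest_pronation = rest_pronation),
                 class = "arm_model")
  rest <- arm_ik(m, rest_hand, rest_pronation)  # errors if unreachable
  m$rest_joints <- rest
  m
}

#' @export
print.arm_model <- function(x, ...) {
  cat("<arm_model> upper arm", x$L1, "cm, forearm", x$L2, "cm; rest hand at (",
      paste(x$rest_hand, collapse = ", "), ") cm\n")
  invisible(x)
}

#' Forward kinematics
#'
#' @param model an [arm_model()].
#' @param q joint state: list or named vector with `plane`, `elevation`,
#'   `axial`, `flexion`, `pronation` in degrees.
#' @return list with `r_humerus`, `r_forearm` (3x3), `elbow`, `hand`
#'   (positions, cm, shoulder frame).
#' @export
arm_fk <- function(model, q) {
  q <- as.list(q)
  R_h <- compose_thoracohumeral(q$plane, q$elevation, q$axial)
  R_f <- R_h %*% compose_elbow_forearm(q$flexion, q$pronation)
  elbow <- as.vector(R_h %*% c(0, -model$L1, 0))
  hand <- elbow + as.vector(R_f %*% c(0, -model$L2, 0))
  list(r_humerus = R_h, r_forearm = R_f, elbow = elbow, hand = hand)
}

#' Inverse kinematics
#'
#' Closed-form and deterministic: the kinematic redundancy is resolved by
#' fixing the plane of elevation to the target azimuth (the humerus and
#' forearm stay in the vertical plane through the shoulder and the hand) and
#' zero humeral axial rotation; elbow flexion follows from the law of
#' cosines and humeral elevation from the in-plane geometry.
#'
#' @param model an [arm_model()].
#' @param hand target hand position, cm, shoulder frame.
#' @param pronation target pronation, deg.
#' @return joint state list (`plane`, `elevation`, `axial`, `flexion`,
#'   `pronation`, degrees) satisfying `arm_fk(model, q)$hand == hand` to
#'   < 0.1 cm.
#' @export
arm_ik <- function(model, hand, pronation) {
  L1 <- model$L1; L2 <- model$L2
  r <- sqrt(sum(hand^2))
  if (r > L1 + L2 - 1e-9 || r < abs(L1 - L2) + 1e-9)
    stop(sprintf("target (%.1f, %.1f, %.1f) cm is out of reach (|p| = %.1f)",
                 hand[1], hand[2], hand[3], r))
  f <- acos(min(1, max(-1, (r^2 - L1^2 - L2^2) / (2 * L1 * L2))))
  # hand in humerus-local coordinates before elevation: (0, -L1 - L2 cos f, -L2 sin f)
  v <- c(0, -L1 - L2 * cos(f), -L2 * sin(f))
  rho <- sqrt(hand[1]^2 + hand[3]^2)
  if (rho < 1e-9) {
    az <- 0                              # hand on the y-axis: plane undefined
    target_yz <- c(hand[2], 0)
  } else {
    az <- atan2(-hand[1], -hand[3])      # azimuth of the (anterior) hand
    target_yz <- c(hand[2], -rho)
  }
  # elevation rotates v (in the x = 0 plane) about x onto (y, z) = target_yz
  b <- atan2(target_yz[2], target_yz[1]) - atan2(v[3], v[2])
  list(plane = wrap_pi(az) * RAD2DEG,
       elevation = wrap_pi(b) * RAD2DEG,
       axial = 0,
       flexion = f * RAD2DEG,
       pronation = pronation)
}
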