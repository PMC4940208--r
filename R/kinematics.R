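#' Joint-angle extraction and rigid-body differential kinematics
#'
#' The shoulder-centred body frame has the x-axis pointing laterally, the
#' y-axis superiorly and the z-axis posteriorly (right-handed). Thoracohumeral
#' motion is described by the ISB-recommended sequence of three Euler
#' rotations -- plane of elevation, elevation angle, axial rotation -- i.e. a
#' Y-X'-Y'' decomposition of the thorax-to-humerus relative rotation. Elbow
#' flexion/extension and forearm pronation/supination come from an X-Y
#' decomposition of the humerus-to-forearm relative rotation: flexion about
#' the humerus local x-axis (mediolateral), pronation about the forearm
#' longitudinal axis. Pronation follows the task convention: 90 deg is the
#' neutral (handshake) orientation, 30 deg is palm-up.
#'
#' All joint angles at these interfaces are in degrees.
#'
#' @name kinematics
NULL

#' Thoracohumeral angles from thorax and humerus orientations
#'
#' Y-X'-Y'' Euler decomposition of the relative rotation
#' \code{t(r_thorax) \%*\% r_humerus}: plane of elevation (about y), elevation
#' (about the rotated x'), axial rotation (about the twice-rotated y'').
#' Elevation is returned in [0, 180]. At gimbal-degenerate poses (elevation
#' near 0 or 180 deg) the plane of elevation and axial rotation are not
#' separately identifiable; the pose is flagged and the plane angle carries
#' the supplied previous value (0 if none), with the axial angle taking the
#' remaining y-rotation.
#'
#' @param r_thorax,r_humerus 3x3 rotation matrices (orientation of each
#'   segment in a common world frame).
#' @param prev_plane plane-of-elevation value (deg) to carry through a
#'   degenerate pose; default 0.
#' @return list with `plane_of_elevation`, `elevation`, `axial_rotation`
#'   (deg) and logical `degenerate`.
#' @export
euler_thoracohumeral <- function(r_thorax, r_humerus, prev_plane = 0) {
  stopifnot(is_rotation(r_thorax, 1e-6), is_rotation(r_humerus, 1e-6))
  R <- t(r_thorax) %*% r_humerus
  a <- yxy_angles(R, prev_first = prev_plane * DEG2RAD)
  list(plane_of_elevation = a[1] * RAD2DEG,
       elevation = a[2] * RAD2DEG,
       axial_rotation = a[3] * RAD2DEG,
       degenerate = attr(a, "degenerate"))
}

# Y-X'-Y'' decomposition: R = Ry(a) %*% Rx(b) %*% Ry(c), b in [0, pi].
yxy_angles <- function(R, prev_first = 0) {
  cb <- min(1, max(-1, R[2, 2]))
  b <- acos(cb)
  degenerate <- sin(b) < 1e-8
  if (degenerate) {
    # R reduces to Ry(a + sign * c); keep first angle, assign rest to third
    a <- prev_first
    total <- atan2(R[1, 3], R[1, 1])   # angle of the residual y-rotation
    # elevation 0: R = Ry(a + c); elevation 180: R = Ry(a - c) Rx(pi)
    cc <- if (cb > 0) total - a else a + total
    out <- c(a, b, wrap_pi(cc))
  } else {
    a <- atan2(R[1, 2], R[3, 2])
    cc <- atan2(R[2, 1], -R[2, 3])
    out <- c(a, b, cc)
  }
  attr(out, "degenerate") <- degenerate
  out
}

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Compose a thoracohumeral rotation from its ISB angles
#'
#' Inverse of [euler_thoracohumeral()] for the relative rotation:
#' `Ry(plane) Rx(elevation) Ry(axial)`.
#'
#' @param plane_of_elevation,elevation,axial_rotation angles in degrees.
#' @return 3x3 rotation matrix (thorax-to-humerus).
#' @export
compose_thoracohumeral <- function(plane_of_elevation, elevation,
                                   axial_rotation) {
  rot_y(plane_of_elevation * DEG2RAD) %*%
    rot_x(elevation * DEG2RAD) %*%
    rot_y(axial_rotation * DEG2RAD)
}

#' Elbow flexion and forearm pronation from humerus and forearm orientations
#'
#' X-Y decomposition of the relative rotation
#' `t(r_humerus) %*% r_forearm = Rx(flexion) %*% Ry(pronation)`:
#' flexion about the humerus mediolateral (x) axis, pronation about the
#' forearm longitudinal (y) axis. Exact for any pose built by
#' [compose_elbow_forearm()]; the decomposition residual is reported so a
#' caller can detect out-of-convention poses.
#'
#' @param r_humerus,r_forearm 3x3 rotation matrices.
#' @return list with `elbow_flexion`, `pronation` (deg).
#' @export
elbow_forearm_angles <- function(r_humerus, r_forearm) {
  stopifnot(is_rotation(r_humerus, 1e-6), is_rotation(r_forearm, 1e-6))
  R <- t(r_humerus) %*% r_forearm
  # R = [[cp, 0, sp], [sf sp, cf, -sf cp], [-cf sp, sf, cf cp]]
  p <- atan2(R[1, 3], R[1, 1])
  f <- atan2(R[3, 2], R[2, 2])
  list(elbow_flexion = f * RAD2DEG, pronation = p * RAD2DEG)
}

#' Compose a humerus-to-forearm rotation from elbow and forearm angles
#'
#' @param elbow_flexion,pronation angles in degrees.
#' @return 3x3 rotation matrix (humerus-to-forearm).
#' @export
compose_elbow_forearm <- function(elbow_flexion, pronation) {
  rot_x(elbow_flexion * DEG2RAD) %*% rot_y(pronation * DEG2RAD)
}

#' Finite-difference body-frame angular velocity
#'
#' The gyroscope channel of a strapped-down inertial unit: the rotation from
#' the orientation at `t` to the orientation at `t + dt`, expressed as a
#' rotation vector in the sensor (body) frame at `t`, divided by `dt`.
#'
#' @param r_t,r_t_plus_dt 3x3 rotation matrices.
#' @param dt time step in seconds, > 0.
#' @return length-3 angular velocity, rad/s, sensor frame.
#' @export
angular_velocity <- function(r_t, r_t_plus_dt, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive scalar")
  dR <- t(r_t) %*% r_t_plus_dt
  rot_to_rotvec(dR) / dt
}

#' Finite-difference specific force (accelerometer reading)
#'
#' What a 3D accelerometer rigidly attached to the sensor reports: the second
#' central difference of the sensor position minus gravity, rotated into the
#' sensor frame. A stationary sensor therefore reads `-g` (magnitude 9.81
#' m/s^2 pointing away from the ground) and a free-falling one reads zero.
#' Endpoint samples use one-sided second differences so the output has the
#' same length as the input.
#'
#' @param p T x 3 matrix of sensor positions (metres, world frame),
#'   uniformly sampled; at least 3 rows.
#' @param r list (length T) of 3x3 sensor orientations.
#' @param dt sample interval, seconds.
#' @param g gravity vector in the world frame, m/s^2; default
#'   `c(0, -9.81, 0)` (y superior).
#' @return T x 3 matrix of accelerometer readings, m/s^2, sensor frame.
#' @export
linear_acceleration <- function(p, r, dt, g = c(0, -9.81, 0)) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 3) stop("need at least 3 position samples")
  stopifnot(length(r) == n, dt > 0)
  a <- matrix(0, n, 3)
  a[2:(n - 1), ] <- (p[3:n, ] - 2 * p[2:(n - 1), ] + p[1:(n - 2), ]) / dt^2
  a[1, ] <- a[2, ]
  a[n, ] <- a[n - 1, ]
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) out[i, ] <- t(r[[i]]) %*% (a[i, ] - g)
  out
}
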