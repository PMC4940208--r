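#' Rotation operators
#'
#' Orientations are represented throughout as 3x3 orthonormal rotation
#' matrices (the canonical internal form). Helpers build elementary rotations
#' about the body axes, compose and invert them, and convert between the
#' axis-angle (rotation-vector) form and the matrix form. Angles at these
#' low-level constructors are in radians; every public joint-angle interface
#' in the package is in degrees.
#'
#' @name rotations
NULL

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Elementary rotations about the x, y and z axes
#'
#' @param theta rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s, c), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, s,
           0, 1, 0,
           -s, 0, c), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, -s, 0,
           s, c, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Identity rotation
#' @return 3x3 identity matrix.
#' @export
rot_identity <- function() diag(3)

#' Axis-angle (rotation vector) to rotation matrix
#'
#' Rodrigues' formula. The rotation vector's direction is the axis and its
#' norm the angle in radians.
#'
#' @param v length-3 rotation vector, radians.
#' @return 3x3 rotation matrix.
#' @export
rot_from_rotvec <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation matrix to axis-angle (rotation vector)
#'
#' Inverse of [rot_from_rotvec()]. Returns the minimal rotation vector
#' (angle in [0, pi]).
#'
#' @param R 3x3 rotation matrix.
#' @return length-3 rotation vector, radians.
#' @export
rot_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (theta > pi - 1e-6) {
    # near-pi: axis from the symmetric part, sign from largest component
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    i <- which.max(axis)
    if (axis[i] > 0) {
      axis <- B[, i] / axis[i]
      axis <- axis / sqrt(sum(axis^2))
    }
    return(axis * theta)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  w / (2 * sin(theta)) * theta
}

#' Re-orthonormalize a near-rotation matrix
#'
#' Projects onto SO(3) via SVD; used to keep long composition chains
#' orthonormal to machine precision.
#'
#' @param R near-orthonormal 3x3 matrix.
#' @return closest 3x3 rotation matrix.
#' @export
rot_orthonormalize <- function(R) {
  s <- svd(R)
  U <- s$u; V <- s$v
  D <- diag(c(1, 1, sign(det(U %*% t(V)))))
  U %*% D %*% t(V)
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(t(R) %*% R - diag(3))) < tol && det(R) > 0
}
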