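# Quaternion and rotation-matrix utilities.
#
# Quaternions are length-4 numeric vectors c(w, x, y, z), unit norm,
# representing the rotation that takes body-frame vectors to the lab frame:
#   v_lab = R(q) %*% v_body.

#' Normalize a quaternion
#' @param q Numeric length-4 (w, x, y, z).
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion product
#'
#' Hamilton product `a * b`: the rotation b followed by a.
#' @param a,b Quaternions (w, x, y, z).
#' @return Quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#' @param q Unit quaternion (w, x, y, z).
#' @return 3x3 rotation matrix mapping body- to lab-frame vectors.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from a rotation matrix
#' @param R 3x3 orthonormal matrix.
#' @return Unit quaternion (w >= 0).
#' @export
matrix_to_quat <- function(R) {
  stopifnot(is_rotation_matrix(R))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

#' Test for a proper rotation matrix
#' @param R Matrix.
#' @param tol Orthonormality tolerance.
#' @return Logical.
#' @export
is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

#' Rotation matrix from axis and angle
#' @param axis Length-3 vector (normalized internally).
#' @param angle Radians.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation aligning one vector with another
#'
#' Returns a rotation matrix Q with `Q %*% from` parallel to `to`.
#' @param from,to Length-3 vectors.
#' @return 3x3 rotation matrix.
#' @export
rotation_aligning <- function(from, to) {
  f <- from / sqrt(sum(from^2)); t <- to / sqrt(sum(to^2))
  c_ <- sum(f * t)
  ax <- c(f[2] * t[3] - f[3] * t[2], f[3] * t[1] - f[1] * t[3],
          f[1] * t[2] - f[2] * t[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-14) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to f
    o <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(f[2] * o[3] - f[3] * o[2], f[3] * o[1] - f[1] * o[3],
            f[1] * o[2] - f[2] * o[1])
    return(axis_angle_matrix(ax, pi))
  }
  axis_angle_matrix(ax, atan2(s, c_))
}

#' Uniform random rotation (as quaternion)
#'
#' Shoemake's method: uniform over SO(3).
#' @param n Number of quaternions.
#' @return If n == 1 a quaternion, else an n x 4 matrix of quaternions.
#' @export
random_quaternion <- function(n = 1) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  q <- cbind(sqrt(1 - u1) * sin(2 * pi * u2),
             sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3),
             sqrt(u1) * cos(2 * pi * u3))
  if (n == 1) q[1, ] else q
}

#' Uniform random rotation matrix
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() quat_to_matrix(random_quaternion(1))
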