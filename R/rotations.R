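# Rotation utilities: SO(3) parameterizations, composition, metrics.
# Convention: rotations act on frequency coordinates as k -> R k; a pose's
# viewing direction is R %*% c(0,0,1) (invariant under in-plane spin), and
# the Hopf parameterization is R = Rz(phi) Ry(theta) Rz(psi) with (theta,
# phi) the viewing direction in spherical coordinates and psi the in-plane
# angle. Angles are radians internally, degrees at every I/O boundary.

#' Elementary rotation matrices
#' @param a angle in radians.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Hopf-coordinate rotation
#' @param theta,phi spherical coordinates of the viewing direction (radians).
#' @param psi in-plane angle (radians).
#' @return 3 x 3 rotation `Rz(phi) Ry(theta) Rz(psi)`.
#' @export
hopf_rotation <- function(theta, phi, psi) {
  rot_z(phi) %*% rot_y(theta) %*% rot_z(psi)
}

#' Geodesic distance between rotations
#' @param Ra,Rb 3 x 3 rotation matrices.
#' @return angle in radians of `Ra^T Rb`, in `[0, pi]`.
#' @export
rot_geodesic <- function(Ra, Rb) {
  tr <- sum(diag(crossprod(Ra, Rb)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2)))
}

#' Validate a rotation matrix
#' @param R candidate matrix.
#' @param tol orthonormality tolerance.
#' @return TRUE invisibly; errors otherwise.
#' @keywords internal
check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != 3L)) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > tol) stop("matrix is not orthonormal")
  if (det(R) < 0) stop("rotation must have det +1 (no reflection)")
  invisible(TRUE)
}

#' Uniform random rotations
#'
#' Samples rotations uniformly (Haar measure) over SO(3) via random unit
#' quaternions, using the current RNG stream.
#'
#' @param n number of rotations.
#' @return list of n 3 x 3 rotation matrices.
#' @export
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    quat_to_rot(q / sqrt(sum(q^2)))
  })
}

#' Quaternion to rotation matrix
#' @param q unit quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Rotation matrix to quaternion
#' @param R 3 x 3 rotation matrix.
#' @return unit quaternion (w, x, y, z) with w >= 0.
#' @export
rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Two-column (6D) rotation parameterization
#'
#' Maps six parameters (two 3-vectors) to a rotation by Gram-Schmidt
#' orthonormalization of the first two columns; the third column is their
#' cross product. This continuous parameterization is used for pose
#' refinement by gradient descent.
#'
#' @param p numeric length-6 vector `(a, b)`.
#' @return 3 x 3 rotation matrix with columns `(c1, c2, c1 x c2)`.
#' @export
rot6_to_matrix <- function(p) {
  a <- p[1:3]; b <- p[4:6]
  c1 <- a / sqrt(sum(a^2))
  u2 <- b - sum(c1 * b) * c1
  c2 <- u2 / sqrt(sum(u2^2))
  c3 <- c(c1[2] * c2[3] - c1[3] * c2[2],
          c1[3] * c2[1] - c1[1] * c2[3],
          c1[1] * c2[2] - c1[2] * c2[1])
  cbind(c1, c2, c3, deparse.level = 0)
}

#' @rdname rot6_to_matrix
#' @param R rotation matrix to initialize from.
#' @return length-6 parameter vector whose `rot6_to_matrix` equals `R`.
#' @export
matrix_to_rot6 <- function(R) c(R[, 1], R[, 2])

#' Gradient of a loss through the 6D parameterization
#'
#' Given dL/dR for `R = rot6_to_matrix(p)`, returns dL/dp. Verified against
#' finite differences in the test suite.
#'
#' @param p length-6 parameter vector.
#' @param dR 3 x 3 matrix of partial derivatives dL/dR.
#' @return length-6 gradient.
#' @keywords internal
rot6_backward <- function(p, dR) {
  a <- p[1:3]; b <- p[4:6]
  na <- sqrt(sum(a^2)); c1 <- a / na
  s <- sum(c1 * b)
  u2 <- b - s * c1; nu <- sqrt(sum(u2^2)); c2 <- u2 / nu
  g1 <- dR[, 1]; g2 <- dR[, 2]; g3 <- dR[, 3]
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  # c3 = c1 x c2
  dc1 <- g1 + cross(c2, g3)
  dc2 <- g2 + cross(g3, c1)
  # c2 = u2 / |u2|
  du2 <- (dc2 - c2 * sum(c2 * dc2)) / nu
  # u2 = b - (c1.b) c1
  db <- du2 - c1 * sum(c1 * du2)
  dc1 <- dc1 - (sum(c1 * du2) * b + s * du2)
  # c1 = a / |a|
  da <- (dc1 - c1 * sum(c1 * dc1)) / na
  c(da, db)
}

#' ZYZ intrinsic Euler angles
#'
#' Decomposes `R = Rz(alpha) Ry(beta) Rz(gamma)`. At the gimbal degeneracy
#' (beta near 0 or pi) only `alpha + gamma` (resp. `alpha - gamma`) is
#' identifiable; the convention here puts the full angle in `gamma`.
#'
#' @param R 3 x 3 rotation matrix.
#' @return named vector `(alpha, beta, gamma)` in radians.
#' @export
euler_zyz <- function(R) {
  beta <- acos(pmin(1, pmax(-1, R[3, 3])))
  if (sin(beta) > 1e-8) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    alpha <- 0
    if (R[3, 3] > 0) gamma <- atan2(R[2, 1], R[1, 1])
    else gamma <- atan2(-R[2, 1], R[1, 1])
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Wrap an angle to (-pi, pi]
#' @param a angle(s) in radians.
#' @return wrapped angle(s).
#' @keywords internal
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  ifelse(w <= -pi, w + 2 * pi, w)
}
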