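# Rigid-body geometry: quaternions, rotation matrices, poses, Kabsch RMSD.

#' Create a rigid pose
#'
#' A pose is a proper rigid transform `x -> R x + t` stored as a unit
#' quaternion plus a translation.
#'
#' @param quaternion length-4 numeric `(w, x, y, z)`; normalized on input.
#' @param translation length-3 numeric, Angstrom.
#' @return An object of class `pose`.
#' @export
pose <- function(quaternion = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(length(quaternion) == 4, length(translation) == 3,
            all(is.finite(quaternion)), all(is.finite(translation)))
  n <- sqrt(sum(quaternion^2))
  if (n < 1e-12) stop("zero quaternion")
  structure(list(q = quaternion / n, t = as.numeric(translation)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("pose: q = [", paste(signif(x$q, 4), collapse = ", "),
      "], t = [", paste(signif(x$t, 4), collapse = ", "), "]\n")
  invisible(x)
}

identity_pose <- function() pose()

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Exponential map: rotation vector (axis * angle) -> rotation matrix.
expmap_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  a <- v / th
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

pose_from_matrix <- function(R, t) pose(matrix_to_quat(R), t)

#' Apply a pose to coordinates
#'
#' @param coords n x 3 matrix.
#' @param p a [pose()].
#' @return transformed n x 3 matrix.
#' @export
apply_pose <- function(coords, p) {
  R <- quat_to_matrix(p$q)
  sweep(coords %*% t(R), 2, p$t, "+")
}

#' Invert a pose
#' @param p a [pose()].
#' @return the inverse pose.
#' @export
invert_pose <- function(p) {
  R <- quat_to_matrix(p$q)
  pose_from_matrix(t(R), -t(R) %*% p$t)
}

compose_poses <- function(p2, p1) {
  # apply p1 first, then p2
  R1 <- quat_to_matrix(p1$q); R2 <- quat_to_matrix(p2$q)
  pose_from_matrix(R2 %*% R1, as.numeric(R2 %*% p1$t + p2$t))
}

# Uniform random rotation (Shoemake); consumes 3 runif draws.
random_quaternion <- function() {
  u <- runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Root-mean-square deviation between two conformations of the same atoms
#' after optimal rigid superposition.
#'
#' @param A,B n x 3 coordinate matrices with matching row order.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, ncol(B) == 3)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  Br <- Bc %*% R
  sqrt(mean(rowSums((Ac - Br)^2)))
}
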