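# Core rigid-body math: unit vectors, orthonormal triads, homogeneous
# transforms, Cardan/Euler decomposition. Angles cross the API in degrees;
# radians are used internally.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Normalize a 3-vector to unit length
#'
#' Implements the normalization bars used throughout the coordinate-system
#' construction tables. Refuses near-zero vectors instead of returning
#' garbage, naming the construction that degenerated.
#'
#' @param v Numeric 3-vector (any units).
#' @param what Label used in the error message when `v` is degenerate.
#' @param tol Degeneracy tolerance on the norm (default 1e-9).
#' @return Unit 3-vector.
#' @export
#' @examples
#' unit3(c(3, 0, 0))
unit3 <- function(v, what = "vector", tol = 1e-9) {
  stopifnot(is.numeric(v), length(v) == 3L)
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n <= tol) {
    stop("degenerate geometry: near-zero ", what, " (norm = ", format(n), ")")
  }
  v / n
}

#' Construct a rigid transform
#'
#' A rigid transform is a proper rotation (3x3, det = +1) plus an origin in
#' mm: the rotation-and-origin pair of the protocol's homogeneous pose
#' matrices. Orthonormality and determinant are validated to 1e-10 unless
#' `check = FALSE`.
#'
#' @param R 3x3 rotation matrix (dimensionless).
#' @param origin Numeric 3-vector (mm).
#' @param check Validate rotation invariants (default TRUE).
#' @return Object of class `rigid_transform` with fields `R` and `origin`.
#' @export
rigid_transform <- function(R = diag(3), origin = c(0, 0, 0), check = TRUE) {
  R <- matrix(as.numeric(R), 3L, 3L)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  if (check) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-10) {
      stop("rotation is not orthonormal within 1e-10")
    }
    if (abs(det(R) - 1) > 1e-10) {
      stop("rotation determinant is not +1 within 1e-10")
    }
  }
  structure(list(R = R, origin = origin), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  origin (mm):", format(x$origin, digits = 6), "\n")
  cat("  rotation:\n")
  print(round(x$R, 6))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf `rigid_transform`.
#' @param p 3-vector or n x 3 matrix of points (mm).
#' @return Transformed points, same shape as `p`.
#' @export
transform_points <- function(tf, p) {
  if (is.matrix(p)) {
    t(tf$R %*% t(p) + tf$origin)
  } else {
    as.numeric(tf$R %*% p + tf$origin)
  }
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @return `rigid_transform` with the inverse mapping.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$R)
  rigid_transform(Rt, -as.numeric(Rt %*% tf$origin), check = FALSE)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` maps local coordinates first through `b`, then
#' through `a` (matrix convention: `T_a %*% T_b`).
#' @param a,b `rigid_transform` objects.
#' @return `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R,
                  as.numeric(a$R %*% b$origin + a$origin),
                  check = FALSE)
}

#' Relative pose of a distal frame with respect to a proximal frame
#'
#' Relative motion between adjacent segments (or mechanical parts) is
#' computed from their global pose matrices as `T_prox^-1 o T_dist`;
#' `relative_transform(T, T)` is the identity.
#'
#' @param t_prox,t_dist `rigid_transform` global poses.
#' @return `rigid_transform` expressing the distal frame in proximal
#'   coordinates.
#' @export
relative_transform <- function(t_prox, t_dist) {
  compose_transforms(invert_transform(t_prox), t_dist)
}

## Elementary rotations (radians, about fixed coordinate axes)
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

.axis_rot <- list(x = rot_x, y = rot_y, z = rot_z)

#' Cardan sequences supported by the protocol
#'
#' `"zxy"` (z, then mobile x', then mobile y'') is used for all joints except
#' ankle-type joints, which use `"zyx"` (z, y', x''). `"rpy"` is the fixed-axes
#' roll-pitch-yaw convention used for segment orientation relative to the
#' ground (equivalent to intrinsic z-y'-x'' read in reverse; here reported as
#' rotations about the fixed lab x (roll), z (pitch, anterior leaning) and y
#' (yaw) axes via the intrinsic y-z'-x'' factorization `R = Ry(yaw) Rz(pitch)
#' Rx(roll)`).
#'
#' @name cardan-sequences
NULL

.sequence_axes <- function(sequence) {
  switch(sequence,
    zxy = c("z", "x", "y"),
    zyx = c("z", "y", "x"),
    rpy = c("y", "z", "x"),
    stop("unknown Cardan sequence: ", sequence)
  )
}

#' Compose a rotation from Cardan angles
#'
#' Intrinsic (mobile-axes) composition: for sequence `zxy`,
#' `R = Rz(a1) %*% Rx(a2) %*% Ry(a3)`.
#'
#' @param angles Numeric 3-vector of angles in degrees.
#' @param sequence One of `"zxy"`, `"zyx"`, `"rpy"`.
#' @return 3x3 rotation matrix.
#' @export
cardan_compose <- function(angles, sequence = "zxy") {
  stopifnot(length(angles) == 3L)
  ax <- .sequence_axes(sequence)
  a <- angles * DEG2RAD
  .axis_rot[[ax[1L]]](a[1L]) %*% .axis_rot[[ax[2L]]](a[2L]) %*%
    .axis_rot[[ax[3L]]](a[3L])
}

#' Decompose a rotation into Cardan angles
#'
#' Intrinsic mobile-axes decomposition in the Grood-Suntay/ISB lineage.
#' Angles are reported in degrees in (-180, 180]. Within `gimbal_tol`
#' degrees of gimbal lock (|a2| = 90 deg) the first and third angles are not
#' separable: they are returned as `NaN` with a warning and a2 as +-90.
#'
#' @param R 3x3 rotation matrix satisfying the `rigid_transform` invariants.
#' @param sequence One of `"zxy"`, `"zyx"`, `"rpy"`.
#' @param gimbal_tol Gimbal-lock proximity tolerance in degrees (default 0.5).
#' @param warn Emit a warning at gimbal lock (default TRUE).
#' @return Numeric 3-vector `(a1, a2, a3)` in degrees;
#'   `cardan_compose(result, sequence)` reproduces `R` to 1e-8 away from
#'   gimbal lock.
#' @export
cardan_decompose <- function(R, sequence = "zxy", gimbal_tol = 0.5,
                             warn = TRUE) {
  ax <- .sequence_axes(sequence)
  key <- paste0(ax, collapse = "")
  # Closed-form extraction per intrinsic sequence. Elements follow from the
  # symbolic product of the three elementary rotations.
  if (key == "zxy") {
    s2 <- R[3L, 2L]
    a2 <- asin(max(-1, min(1, s2)))
    if (abs(abs(s2) - 1) < .gimbal_sin(gimbal_tol)) {
      if (warn) warning("gimbal lock in zxy decomposition: a1/a3 undefined")
      return(c(NaN, sign(s2) * 90, NaN))
    }
    a1 <- atan2(-R[1L, 2L], R[2L, 2L])
    a3 <- atan2(-R[3L, 1L], R[3L, 3L])
  } else if (key == "zyx") {
    s2 <- -R[3L, 1L]
    a2 <- asin(max(-1, min(1, s2)))
    if (abs(abs(s2) - 1) < .gimbal_sin(gimbal_tol)) {
      if (warn) warning("gimbal lock in zyx decomposition: a1/a3 undefined")
      return(c(NaN, sign(s2) * 90, NaN))
    }
    a1 <- atan2(R[2L, 1L], R[1L, 1L])
    a3 <- atan2(R[3L, 2L], R[3L, 3L])
  } else if (key == "yzx") { # rpy: R = Ry(a1) Rz(a2) Rx(a3)
    s2 <- R[2L, 1L]
    a2 <- asin(max(-1, min(1, s2)))
    if (abs(abs(s2) - 1) < .gimbal_sin(gimbal_tol)) {
      if (warn) warning("gimbal lock in rpy decomposition: yaw/roll undefined")
      return(c(NaN, sign(s2) * 90, NaN))
    }
    a1 <- atan2(-R[3L, 1L], R[1L, 1L])
    a3 <- atan2(-R[2L, 3L], R[2L, 2L])
  } else {
    stop("unknown sequence key: ", key)
  }
  c(a1, a2, a3) * RAD2DEG
}

.gimbal_sin <- function(gimbal_tol) {
  # |sin(a2)| within this of 1 <=> |a2| within gimbal_tol deg of 90
  1 - sin((90 - gimbal_tol) * DEG2RAD)
}

#' Roll-pitch-yaw orientation of a segment with respect to the ground
#'
#' Segment orientation is the decomposition of the local frame's rotation
#' with respect to the lab frame, reported as (roll, pitch, yaw) in degrees:
#' pitch is rotation about the lab lateral axis (anterior leaning positive),
#' roll about the forward axis, yaw about the vertical axis, via
#' `R = Ry(yaw) Rz(pitch) Rx(roll)`.
#'
#' @param R 3x3 rotation of the segment frame in lab coordinates.
#' @inheritParams cardan_decompose
#' @return `(roll, pitch, yaw)` in degrees.
#' @export
rpy_decompose <- function(R, gimbal_tol = 0.5, warn = TRUE) {
  a <- cardan_decompose(R, "rpy", gimbal_tol = gimbal_tol, warn = warn)
  # rpy sequence returns (yaw, pitch, roll) in decomposition order
  c(a[3L], a[2L], a[1L])
}

#' @rdname rpy_decompose
#' @param rpy `(roll, pitch, yaw)` degrees.
#' @export
rpy_compose <- function(rpy) {
  cardan_compose(c(rpy[3L], rpy[2L], rpy[1L]), "rpy")
}

#' Random rotation matrices (uniform on SO(3))
#'
#' Utility for property tests and equivariance checks.
#' @param n Number of rotations.
#' @return List of 3x3 rotation matrices.
#' @export
random_rotations <- function(n = 1L) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
    ), 3L, 3L)
  })
}
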