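#' Rigid transforms in 3-d
#'
#' A rigid transform is a proper rotation plus a translation, acting on world
#' coordinates in millimetres as \eqn{T(x) = R x + t}. It is the unit of all
#' registration output in ctmotion: bone and implant registrations, patient
#' repositioning, and the implant-versus-bone migration are all rigid
#' transforms.
#'
#' @param rotation 3x3 proper orthonormal matrix (\eqn{R^T R = I},
#'   \eqn{\det R = +1}).
#' @param translation numeric length-3 translation in mm.
#' @param tol tolerance for the orthonormality / determinant check.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' T1 <- rigid_transform(diag(3), c(1, 2, 3))
#' rt_apply(T1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-6) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  if (length(translation) != 3L || anyNA(translation))
    stop("translation must be a finite length-3 vector", call. = FALSE)
  ortho <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho > tol)
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.3g)", ortho),
         call. = FALSE)
  d <- det(rotation)
  if (abs(d - 1) > tol)
    stop(sprintf("rotation is not proper (det = %.6f, expected +1)", d),
         call. = FALSE)
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rt_rotation_angle(x)
  cat(sprintf("<rigid_transform>  |t| = %.4f mm, rotation angle = %.4f deg\n",
              sqrt(sum(x$t^2)), ang))
  cat("rotation:\n")
  print(round(x$R, 6))
  cat("translation (mm): ", paste(sprintf("%.6f", x$t), collapse = ", "), "\n")
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points numeric length-3 vector or n x 3 matrix of points (mm).
#' @return Points of the same shape, transformed.
#' @export
rt_apply <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(dim(points))) {
    drop(transform$R %*% as.numeric(points)) + transform$t
  } else {
    p <- as.matrix(points)
    stopifnot(ncol(p) == 3L)
    sweep(p %*% t(transform$R), 2L, transform$t, "+")
  }
}

#' Compose rigid transforms
#'
#' `rt_compose(a, b)` returns the transform applying `b` first, then `a`
#' (i.e. \eqn{a \circ b}).
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$R %*% b$R, drop(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$R)
  rigid_transform(Rt, drop(-Rt %*% transform$t))
}

#' Rotation angle of a rigid transform
#'
#' The total rotation angle (degrees) about the transform's screw axis,
#' recovered from the trace of the rotation matrix.
#'
#' @param transform a `rigid_transform`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
rt_rotation_angle <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- transform$R
  c_ang <- min(1, max(-1, (sum(diag(R)) - 1) / 2))
  # |sin| from the skew part: ||R - R^T||_F = 2 sqrt(2) |sin(theta)|
  s_ang <- min(1, sqrt(sum((R - t(R))^2)) / (2 * sqrt(2)))
  # atan2 is well-conditioned at both ends, unlike acos near theta = 0
  atan2(s_ang, c_ang) * 180 / pi
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Build a rigid transform from Cardan angles
#'
#' Angles are applied about the fixed (extrinsic) world axes in the order
#' x, then y, then z, so the rotation matrix is
#' \eqn{R = R_z(r_z) R_y(r_y) R_x(r_x)}. This is the default angle convention
#' used throughout the package; see [decompose_6dof()] for the inverse.
#'
#' @param angles_deg numeric length-3, rotations about x, y, z in degrees.
#' @param translation numeric length-3 translation in mm.
#' @param order `"xyz"` (default, fixed-frame x then y then z) or `"zyx"`.
#' @return A `rigid_transform`.
#' @export
rt_from_euler <- function(angles_deg, translation = c(0, 0, 0),
                          order = c("xyz", "zyx")) {
  order <- match.arg(order)
  a <- as.numeric(angles_deg)
  stopifnot(length(a) == 3L)
  R <- if (order == "xyz") {
    rot_z(a[3]) %*% rot_y(a[2]) %*% rot_x(a[1])
  } else {
    rot_x(a[1]) %*% rot_y(a[2]) %*% rot_z(a[3])
  }
  rigid_transform(R, translation)
}

#' Extract Cardan angles from a rotation matrix
#'
#' Inverse of [rt_from_euler()]: for `order = "xyz"` solves
#' \eqn{R = R_z(r_z) R_y(r_y) R_x(r_x)} for the three angles. Near gimbal
#' lock (\eqn{|r_y|} within `gimbal_tol_deg` of 90 degrees) the returned
#' vector carries attribute `gimbal = TRUE`.
#'
#' @param R 3x3 proper rotation matrix.
#' @param order `"xyz"` or `"zyx"` (fixed-frame application order).
#' @param gimbal_tol_deg proximity to 90 degrees that triggers the gimbal
#'   flag (default 0.1).
#' @return Length-3 numeric vector of angles in degrees, each in
#'   (-180, 180\].
#' @export
euler_angles <- function(R, order = c("xyz", "zyx"), gimbal_tol_deg = 0.1) {
  order <- match.arg(order)
  stopifnot(all(dim(R) == c(3L, 3L)))
  r2d <- 180 / pi
  if (order == "xyz") {
    sy <- -R[3, 1]
    sy <- min(1, max(-1, sy))
    ry <- asin(sy) * r2d
    if (abs(abs(ry) - 90) < gimbal_tol_deg) {
      # gimbal: rx and rz are not separable; conventionally fold into rz
      rx <- 0
      rz <- atan2(-R[1, 2], R[2, 2]) * r2d
      ang <- c(rx, ry, rz)
      attr(ang, "gimbal") <- TRUE
      return(ang)
    }
    rx <- atan2(R[3, 2], R[3, 3]) * r2d
    rz <- atan2(R[2, 1], R[1, 1]) * r2d
  } else {
    sy <- R[1, 3]
    sy <- min(1, max(-1, sy))
    ry <- asin(sy) * r2d
    if (abs(abs(ry) - 90) < gimbal_tol_deg) {
      rz <- 0
      rx <- atan2(R[2, 1], R[2, 2]) * r2d
      ang <- c(rx, ry, rz)
      attr(ang, "gimbal") <- TRUE
      return(ang)
    }
    rx <- atan2(-R[2, 3], R[3, 3]) * r2d
    rz <- atan2(-R[1, 2], R[1, 1]) * r2d
  }
  ang <- c(rx, ry, rz)
  attr(ang, "gimbal") <- FALSE
  ang
}

#' Serialise / deserialise rigid transforms as JSON-friendly lists
#'
#' The rotation is stored row-major as a length-9 vector, the translation in
#' mm, matching the package's on-disk JSON layout.
#'
#' @param transform a `rigid_transform`.
#' @return `rt_to_list()`: a plain list; `rt_from_list()`: a
#'   `rigid_transform`.
#' @export
rt_to_list <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  list(rotation_row_major = as.numeric(t(transform$R)),
       translation_mm = as.numeric(transform$t))
}

#' @rdname rt_to_list
#' @param x a list as produced by `rt_to_list()`.
#' @export
rt_from_list <- function(x) {
  rigid_transform(matrix(as.numeric(x$rotation_row_major), 3, 3, byrow = TRUE),
                  as.numeric(x$translation_mm))
}

# uniform random unit vector (uses the current RNG stream)
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Sample a random patient-repositioning transform
#'
#' Draws a uniform random rigid transform within the given bounds: the
#' rotation axis is uniform on the sphere with angle uniform in
#' \[0, `max_rotation_deg`\], and the translation is uniform in the ball of
#' radius `max_translation_mm`. Models the repositioning of the patient in
#' the scanner between the two examinations of a double-examination
#' protocol. The true repositioning magnitude between clinical double CT
#' exams is not standardised; the defaults are deliberately generous and
#' configurable.
#'
#' @param max_translation_mm maximum translation norm in mm (default 20).
#' @param max_rotation_deg maximum rotation angle in degrees (default 10).
#' @param seed integer seed; the same seed always yields the same transform.
#' @return A `rigid_transform`.
#' @export
sample_repositioning <- function(max_translation_mm = 20,
                                 max_rotation_deg = 10, seed) {
  if (max_translation_mm < 0 || max_rotation_deg < 0)
    stop("repositioning bounds must be non-negative", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("seed is required", call. = FALSE)
  if (max_translation_mm == 0 && max_rotation_deg == 0) return(rt_identity())
  withr::with_seed(as.integer(seed), {
    axis <- random_unit_vector()
    angle <- stats::runif(1, 0, max_rotation_deg)
    tdir <- random_unit_vector()
    tnorm <- max_translation_mm * stats::runif(1)^(1 / 3)
    rigid_transform(rotation_about_axis(axis, angle), tdir * tnorm)
  })
}
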