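#' @title Vector-geometry kernel for skeleton angle computation
#' @name geometry
#' @description
#' All RULA angle constructions in this package reduce to four primitives:
#' the angle between two vectors, the angle between consecutive segment
#' vectors of a three-joint chain, the normal vector of the plane spanned by
#' three joints, and the angle between two plane normals. Angles are
#' reported in degrees because every scoring threshold is stated in degrees.
NULL

# Relative tolerance below which a vector/triple is treated as degenerate.
.EG_COLLINEAR_TOL <- 1e-9

.eg_norm <- function(v) sqrt(sum(v * v))

#' Angle between two 3D vectors
#'
#' Computes \eqn{\theta = \arccos(a \cdot b / (|a||b|))} in degrees. The
#' cosine is clamped to \eqn{[-1, 1]} before the arccosine so that finite
#' inputs can never raise a numeric domain error.
#'
#' @param a,b numeric length-3 vectors with positive norm.
#' @return angle in degrees, in \eqn{[0, 180]}.
#' @examples
#' vector_angle(c(1, 0, 0), c(0, 1, 0)) # 90
#' vector_angle(c(1, 1, 0), c(1, 0, 0)) # 45
#' @export
vector_angle <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3L, length(b) == 3L)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("vector_angle: inputs must be finite", call. = FALSE)
  na <- .eg_norm(a); nb <- .eg_norm(b)
  if (na <= 0 || nb <= 0)
    stop("vector_angle: degenerate geometry (zero-norm vector)", call. = FALSE)
  ct <- sum(a * b) / (na * nb)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' Angle of a three-joint chain
#'
#' Angle between the two segment vectors \eqn{b - a} and \eqn{c - b} of the
#' joint chain a-b-c. Note this is the supplement of the interior angle at
#' the middle joint: a straight continuation reads 0 degrees.
#'
#' @param a,b,c numeric length-3 joint positions; `b != a` and `c != b`.
#' @return angle in degrees, in \eqn{[0, 180]}.
#' @examples
#' three_point_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)) # 0 (collinear)
#' three_point_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)) # 90
#' @export
three_point_angle <- function(a, b, c) {
  v1 <- as.numeric(b) - as.numeric(a)
  v2 <- as.numeric(c) - as.numeric(b)
  if (.eg_norm(v1) <= 0 || .eg_norm(v2) <= 0)
    stop("three_point_angle: degenerate geometry (coincident points)", call. = FALSE)
  vector_angle(v1, v2)
}

#' Interior angle at the middle joint of a three-joint chain
#'
#' Angle at vertex `b` between the directions towards `a` and towards `c`,
#' i.e. the supplement of [three_point_angle()]. A hanging upper arm reads
#' approximately 0 against the shoulder-to-hip direction under this
#' convention.
#'
#' @inheritParams three_point_angle
#' @return angle in degrees, in \eqn{[0, 180]}.
#' @export
interior_angle <- function(a, b, c) {
  v1 <- as.numeric(a) - as.numeric(b)
  v2 <- as.numeric(c) - as.numeric(b)
  if (.eg_norm(v1) <= 0 || .eg_norm(v2) <= 0)
    stop("interior_angle: degenerate geometry (coincident points)", call. = FALSE)
  vector_angle(v1, v2)
}

#' Normal vector of the plane through three joints
#'
#' \eqn{NV = (b - a) \times (c - a)}. Orientation follows operand order:
#' swapping `b` and `c` negates the result.
#'
#' @inheritParams three_point_angle
#' @return numeric length-3 normal vector (not normalised).
#' @examples
#' normal_vector(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) # c(0, 0, 1)
#' @export
normal_vector <- function(a, b, c) {
  a <- as.numeric(a)
  u <- as.numeric(b) - a
  v <- as.numeric(c) - a
  nv <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  scale <- max(.eg_norm(u), .eg_norm(v))
  if (scale <= 0 || .eg_norm(nv) < .EG_COLLINEAR_TOL * scale * scale)
    stop("normal_vector: degenerate geometry (collinear joints)", call. = FALSE)
  nv
}

#' Angle between two planes
#'
#' The angle between two plane normals, used for the pronation-supination
#' (wrist twist) measurement between the calibration palm plane and the
#' current palm plane.
#'
#' @param n1,n2 numeric length-3 plane normals (non-zero).
#' @return angle in degrees, in \eqn{[0, 180]}.
#' @export
plane_angle <- function(n1, n2) vector_angle(n1, n2)

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a rotation of `theta` degrees about `axis`.
#' Used by the synthetic-pose generator and by the rigid-motion invariance
#' tests.
#'
#' @param axis numeric length-3 axis (any non-zero norm).
#' @param theta rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, theta) {
  axis <- as.numeric(axis)
  n <- .eg_norm(axis)
  if (n <= 0) stop("rotation_matrix: zero axis", call. = FALSE)
  u <- axis / n
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}
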