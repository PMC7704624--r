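# Small 3D geometry toolkit: vectors, rigid transforms, lines and planes.
# All lengths are millimetres throughout the package.

vnorm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors
#'
#' @param a,b Numeric 3-vectors.
#' @param degrees Return degrees (default) instead of radians.
#' @return Angle in `[0, 180]` degrees (or `[0, pi]` radians).
#' @export
angle_between <- function(a, b, degrees = TRUE) {
  ca <- sum(unitize(a) * unitize(b))
  ang <- acos(max(-1, min(1, ca)))
  if (degrees) ang * 180 / pi else ang
}

# angle between undirected lines, in [0, 90] degrees
line_angle <- function(a, b) {
  ang <- angle_between(a, b)
  min(ang, 180 - ang)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; the axis need not be unit length.
#'
#' @param axis Numeric 3-vector, rotation axis.
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- unitize(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# intrinsic x-y-z Euler composition: R = Rx(a) %*% Ry(b) %*% Rz(c)
euler_xyz_to_matrix <- function(a_deg, b_deg, c_deg) {
  rotation_about(c(1, 0, 0), a_deg) %*%
    rotation_about(c(0, 1, 0), b_deg) %*%
    rotation_about(c(0, 0, 1), c_deg)
}

# inverse of the above; returns degrees; flags gimbal proximity
matrix_to_euler_xyz <- function(R) {
  # R = Rx(a) Ry(b) Rz(c):
  #   R[1,3] =  sin(b)
  #   R[1,2] = -cos(b) sin(c),  R[1,1] = cos(b) cos(c)
  #   R[2,3] = -sin(a) cos(b),  R[3,3] = cos(a) cos(b)
  b <- asin(max(-1, min(1, R[1, 3])))
  gimbal <- abs(cos(b)) < 1e-9
  if (gimbal) {
    a <- atan2(R[2, 1], R[2, 2])
    c <- 0
  } else {
    a <- atan2(-R[2, 3], R[3, 3])
    c <- atan2(-R[1, 2], R[1, 1])
  }
  list(angles = rad2deg(c(a, b, c)), gimbal = gimbal)
}

# --------------------------------------------------------------------------
# Rigid transforms
# --------------------------------------------------------------------------

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric 3-vector in mm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation has negative determinant (reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Compose rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The exact inverse transform.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

#' Apply a rigid transform to points
#' @param tf A `rigid_transform`.
#' @param pts Nx3 matrix (or a single 3-vector) of points.
#' @return Transformed points, same shape as input.
#' @export
transform_points <- function(tf, pts) {
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, 1, 3)
  out <- pts %*% t(tf$rotation)
  out <- sweep(out, 2, tf$translation, "+")
  if (single) as.numeric(out) else out
}

#' Apply only the rotation of a rigid transform to direction vectors
#' @param tf A `rigid_transform`.
#' @param dirs Nx3 matrix or 3-vector of directions.
#' @return Rotated directions.
#' @export
transform_directions <- function(tf, dirs) {
  single <- is.null(dim(dirs))
  if (single) dirs <- matrix(dirs, 1, 3)
  out <- dirs %*% t(tf$rotation)
  if (single) as.numeric(out) else out
}

# --------------------------------------------------------------------------
# Lines and planes
# --------------------------------------------------------------------------

#' 3D line through a point
#' @param point Numeric 3-vector on the line (mm).
#' @param direction Direction vector; normalized on construction.
#' @return Object of class `line3`.
#' @export
line3 <- function(point, direction) {
  structure(list(point = as.numeric(point), direction = unitize(direction)),
            class = "line3")
}

#' 3D plane through a point
#' @param point Numeric 3-vector on the plane (mm).
#' @param normal Normal vector; normalized on construction.
#' @return Object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unitize(normal)),
            class = "plane3")
}

#' @export
print.line3 <- function(x, ...) {
  cat("<line3> point (", paste(round(x$point, 3), collapse = ", "),
      ") direction (", paste(round(x$direction, 6), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.plane3 <- function(x, ...) {
  cat("<plane3> point (", paste(round(x$point, 3), collapse = ", "),
      ") normal (", paste(round(x$normal, 6), collapse = ", "), ")\n")
  invisible(x)
}

transform_line <- function(tf, line) {
  line3(transform_points(tf, line$point), transform_directions(tf, line$direction))
}

transform_plane <- function(tf, plane) {
  plane3(transform_points(tf, plane$point), transform_directions(tf, plane$normal))
}

# signed distances of points to a plane (positive on the normal side)
plane_signed_distance <- function(plane, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  as.numeric(sweep(pts, 2, plane$point, "-") %*% plane$normal)
}

# foot of the perpendicular from line a to line b, on line a (closed form)
closest_point_on_line_to_line <- function(a, b) {
  d1 <- a$direction; d2 <- b$direction
  r <- b$point - a$point
  d12 <- sum(d1 * d2)
  denom <- 1 - d12^2
  if (abs(denom) < 1e-12) stop("lines are parallel")
  t1 <- (sum(r * d1) - d12 * sum(r * d2)) / denom
  a$point + t1 * d1
}

project_point_on_line <- function(line, p) {
  line$point + sum((p - line$point) * line$direction) * line$direction
}

# total-least-squares line through points: returns line3 through centroid
fit_line_tls <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x, nu = 0, nv = 3)
  line3(ctr, sv$v[, 1])
}

# total-least-squares plane through points
fit_plane_tls <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate plane fit: points are collinear")
  plane3(ctr, sv$v[, 3])
}

# orthonormal basis (u, v) spanning the plane orthogonal to n
plane_basis <- function(n) {
  n <- unitize(n)
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(cross3(n, seed))
  v <- cross3(n, u)
  list(u = u, v = v)
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}
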