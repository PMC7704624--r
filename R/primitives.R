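# Least-squares geometric primitives used by the refinement stages.
# All fits center the data first and use rotation-invariant normalizations,
# so results are equivariant under rigid transforms of the input points.

#' Least-squares sphere fit
#'
#' Algebraic (linear) solution followed by geometric Gauss-Newton
#' refinement of the orthogonal residuals.  Exact on noiseless samples.
#'
#' @param points Nx3 matrix, N >= 4, not coplanar.
#' @return List with `center`, `radius`, `rms_residual` (geometric) and
#'   `rms_algebraic`.
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("sphere fit needs at least 4 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  A <- cbind(2 * x, 1)
  rhs <- rowSums(x^2)
  qr_ <- qr(A)
  if (qr_$rank < 4) stop("degenerate sphere fit: points are coplanar")
  # guard against numerically near-coplanar input
  d <- abs(diag(qr.R(qr_)))
  if (min(d) < 1e-9 * max(d)) stop("degenerate sphere fit: points are coplanar")
  sol <- qr.coef(qr_, rhs)
  c0 <- sol[1:3]
  r0 <- sqrt(sol[4] + sum(c0^2))
  alg_res <- sqrt(mean((sqrt(rowSums(sweep(x, 2, c0)^2)) - r0)^2))
  # Gauss-Newton on (|p - c| - r)
  cc <- c0; rr <- r0
  for (it in 1:20) {
    diff <- sweep(x, 2, cc)
    dist <- sqrt(rowSums(diff^2))
    J <- cbind(-diff / pmax(dist, 1e-12), -1)
    res <- dist - rr
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) rep(0, 4))
    step[is.na(step)] <- 0
    cc <- cc + step[1:3]
    rr <- rr + step[4]
    if (max(abs(step)) < 1e-12) break
  }
  dist <- sqrt(rowSums(sweep(x, 2, cc)^2))
  list(center = cc + ctr, radius = rr,
       rms_residual = sqrt(mean((dist - rr)^2)),
       rms_algebraic = alg_res)
}

#' Least-squares ellipse fit to near-coplanar 3D points
#'
#' Fits a total-least-squares plane, projects the points in-plane and fits
#' a conic by the numerically stable direct ellipse-specific least squares
#' of Halir & Flusser; errors out when the conic is not an ellipse.
#'
#' @param points Nx3 matrix, N >= 6.
#' @return List with `center` (3-vector), `normal`, `major_axis_dir`,
#'   `semi_major`, `semi_minor`, `foci` (2x3 matrix) and `rms_residual`
#'   (in-plane algebraic distance proxy).
#' @export
fit_ellipse_3d <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6) stop("ellipse fit needs at least 6 points")
  plane <- fit_plane_tls(points)
  b <- plane_basis(plane$normal)
  rel <- sweep(points, 2, plane$point)
  u <- as.numeric(rel %*% b$u)
  v <- as.numeric(rel %*% b$v)
  fit <- fit_ellipse_2d(u, v)
  center3 <- plane$point + fit$center[1] * b$u + fit$center[2] * b$v
  major3 <- unitize(fit$major_dir[1] * b$u + fit$major_dir[2] * b$v)
  cdist <- sqrt(max(fit$a^2 - fit$b^2, 0))
  foci <- rbind(center3 + cdist * major3, center3 - cdist * major3)
  list(center = center3, normal = plane$normal, major_axis_dir = major3,
       semi_major = fit$a, semi_minor = fit$b, foci = foci,
       rms_residual = fit$rms)
}

# Halir & Flusser direct ellipse fit in 2D (centered internally)
fit_ellipse_2d <- function(u, v) {
  mu <- mean(u); mv <- mean(v)
  x <- u - mu; y <- v - mv
  if (max(abs(x)) < 1e-12 && max(abs(y)) < 1e-12)
    stop("degenerate ellipse fit: points coincide")
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate ellipse fit: points are collinear"))
  M <- S1 + S2 %*% T_
  # premultiply by inv(C1) with constraint matrix C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vals <- Re(ev$values)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0) stop("conic fit is not an ellipse")
  a1 <- vecs[, ok[1]]
  coef <- c(a1, as.numeric(T_ %*% a1))  # (A, B, C, D, E, F)
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F_ <- coef[6]
  A2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ctr <- tryCatch(solve(2 * A2, -c(D, E)), error = function(e)
    stop("conic fit is degenerate"))
  q0 <- F_ + sum(c(D, E) * ctr) / 2
  ee <- eigen(A2, symmetric = TRUE)
  ax2 <- -q0 / ee$values
  if (any(ax2 <= 0)) stop("conic fit is not an ellipse")
  semis <- sqrt(ax2)
  ord <- order(semis, decreasing = TRUE)
  major_dir <- ee$vectors[, ord[1]]
  vals_uv <- cbind(x^2, x * y, y^2, x, y, 1) %*% coef
  list(center = ctr + c(mu, mv), a = semis[ord[1]], b = semis[ord[2]],
       major_dir = major_dir, rms = sqrt(mean(vals_uv^2)))
}

#' Least-squares ellipsoid fit
#'
#' Algebraic least-squares quadric fit constrained to an ellipsoid
#' (Li-Griffiths constraint 4J - I^2 = 1 on the quadratic-form invariants,
#' which is rotation-invariant and excludes hyperboloids/paraboloids even
#' on near-cylindrical data); data are centered first, so the fit is
#' equivariant under rigid transforms.
#'
#' @param points Nx3 matrix, N >= 9, spanning 3D.
#' @return List with `center`, `axes` (3x3, columns = unit directions,
#'   right-handed), `radii` (sorted descending) and `rms_residual`
#'   (algebraic).
#' @export
fit_ellipsoid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 9) stop("ellipsoid fit needs at least 9 points")
  ctr <- colMeans(points)
  scl <- mean(sqrt(rowSums(sweep(points, 2, ctr)^2)))
  if (scl < 1e-12) stop("degenerate ellipsoid fit: points coincide")
  p <- sweep(points, 2, ctr) / scl
  # design ordering: (a, b, c, f, g, h, p, q, r, d) for
  # a x^2 + b y^2 + c z^2 + 2f yz + 2g xz + 2h xy + 2p x + 2q y + 2r z + d
  D <- cbind(p[, 1]^2, p[, 2]^2, p[, 3]^2,
             2 * p[, 2] * p[, 3], 2 * p[, 1] * p[, 3], 2 * p[, 1] * p[, 2],
             2 * p[, 1], 2 * p[, 2], 2 * p[, 3], 1)
  sv <- svd(D, nu = 0)
  if (sv$d[9] < 1e-9 * sv$d[1])
    stop("degenerate ellipsoid fit: points do not span 3D")
  S <- crossprod(D)
  S11 <- S[1:6, 1:6]; S12 <- S[1:6, 7:10]; S22 <- S[7:10, 7:10]
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- matrix(c(-1, 1, 1, 1, -1, 1, 1, 1, -1), 3, 3)
  C[4:6, 4:6] <- diag(-4, 3)
  S22i <- tryCatch(solve(S22), error = function(e)
    stop("degenerate ellipsoid fit: points do not span 3D"))
  M <- solve(C, S11 - S12 %*% S22i %*% t(S12))
  ee0 <- eigen(M)
  vals <- Re(ee0$values)
  # the ellipsoid solution carries the single largest (non-negative up to
  # rounding) generalized eigenvalue; all others are negative
  v1 <- Re(ee0$vectors[, which.max(vals)])
  v2 <- as.numeric(-S22i %*% t(S12) %*% v1)
  th <- c(v1, v2)
  A <- matrix(c(th[1], th[6], th[5],
                th[6], th[2], th[4],
                th[5], th[4], th[3]), 3, 3)
  bvec <- 2 * th[7:9]
  f0 <- th[10]
  c0 <- tryCatch(solve(2 * A, -bvec), error = function(e)
    stop("quadric fit is degenerate"))
  q0 <- f0 + sum(bvec * c0) / 2
  ee <- eigen(A, symmetric = TRUE)
  r2 <- -q0 / ee$values
  if (any(r2 <= 0)) stop("quadric fit is not an ellipsoid")
  radii <- sqrt(r2)
  ord <- order(radii, decreasing = TRUE)
  # near-spherical tie-break: lexicographic axis direction order
  if (radii[ord[1]] - radii[ord[2]] < 1e-6 * radii[ord[1]]) {
    key <- apply(round(abs(ee$vectors), 9), 2, paste, collapse = ",")
    ord <- order(-round(radii, 9), key)
  }
  axes <- ee$vectors[, ord, drop = FALSE]
  # deterministic signs, right-handed completion
  for (j in 1:2) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  axes[, 3] <- cross3(axes[, 1], axes[, 2])
  res <- as.numeric(D %*% th)
  list(center = c0 * scl + ctr, axes = axes, radii = radii[ord] * scl,
       rms_residual = sqrt(mean(res^2)) * scl)
}
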