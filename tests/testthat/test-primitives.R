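# Least-squares sphere / ellipse / ellipsoid fits.

test_that("sphere fit is exact on noiseless samples and rejects coplanar", {
  # regular tetrahedron inscribed in the unit sphere
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  fit <- fit_sphere(tet)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  set.seed(3)
  u <- matrix(rnorm(600), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * 24, 2, c(10, -5, 3), "+")
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(10, -5, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 24, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
  coplanar <- cbind(matrix(rnorm(20), ncol = 2), 0)
  expect_error(fit_sphere(coplanar), "coplanar")
})

test_that("sphere fit is robust to measurement noise", {
  set.seed(11)
  u <- matrix(rnorm(1500), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * 24 + matrix(rnorm(1500, sd = 0.1), ncol = 3)
  fit <- fit_sphere(pts)
  expect_lt(femcoord:::vnorm(fit$center), 0.1)
})

test_that("3D ellipse fit recovers plane, axes and foci", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  pts <- cbind(5 * cos(th), 3 * sin(th), 2)
  fit <- fit_ellipse_3d(pts)
  expect_equal(fit$semi_major, 5, tolerance = 1e-6)
  expect_equal(fit$semi_minor, 3, tolerance = 1e-6)
  expect_equal(fit$center, c(0, 0, 2), tolerance = 1e-6)
  expect_equal(abs(fit$normal[3]), 1, tolerance = 1e-9)
  cfoc <- sqrt(25 - 9)
  expect_equal(sort(fit$foci[, 1]), c(-cfoc, cfoc), tolerance = 1e-6)
  # circle limit: both semi-axes equal, foci coincide at the center
  circ <- cbind(4 * cos(th), 4 * sin(th), -1)
  fc <- fit_ellipse_3d(circ)
  expect_equal(fc$semi_major, fc$semi_minor, tolerance = 1e-6)
  expect_lt(femcoord:::vnorm(fc$foci[1, ] - fc$foci[2, ]), 1e-4)
  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(fit_ellipse_3d(line), "collinear")
})

test_that("ellipsoid fit recovers radii/axes and rejects degenerate input", {
  set.seed(5)
  u <- matrix(rnorm(900), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(sweep(u, 2, c(40, 8, 8), "*"), 2, c(5, -3, 2), "+")
  fit <- fit_ellipsoid(pts)
  expect_equal(fit$radii, c(40, 8, 8), tolerance = 1e-6)
  expect_equal(fit$center, c(5, -3, 2), tolerance = 1e-6)
  expect_equal(abs(fit$axes[1, 1]), 1, tolerance = 1e-6)
  # sphere samples: all radii equal (any orthonormal axes accepted)
  fs <- fit_ellipsoid(u * 10)
  expect_equal(fs$radii, rep(10, 3), tolerance = 1e-6)
  expect_equal(crossprod(fs$axes), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  planar <- cbind(u[, 1:2], 0)
  expect_error(fit_ellipsoid(planar), "span 3D")
})

test_that("fits are equivariant under rigid transforms", {
  set.seed(9)
  u <- matrix(rnorm(450), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sph <- u * 24 + matrix(rnorm(450, sd = 0.1), ncol = 3)
  ell3 <- sweep(u, 2, c(40, 8, 8), "*") + matrix(rnorm(450, sd = 0.05),
                                                 ncol = 3)
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  ell2 <- cbind(5 * cos(th), 3 * sin(th), 2) +
    matrix(rnorm(180, sd = 0.01), ncol = 3)
  f0s <- fit_sphere(sph)
  f0e <- fit_ellipsoid(ell3)
  f0p <- fit_ellipse_3d(ell2)
  for (tf in random_transforms(3, seed = 21)) {
    fs <- fit_sphere(transform_points(tf, sph))
    expect_equal(fs$center, transform_points(tf, f0s$center),
                 tolerance = 1e-9)
    expect_equal(fs$radius, f0s$radius, tolerance = 1e-9)
    fe <- fit_ellipsoid(transform_points(tf, ell3))
    expect_equal(fe$center, transform_points(tf, f0e$center),
                 tolerance = 1e-7)
    expect_equal(fe$radii, f0e$radii, tolerance = 1e-7)
    fp <- fit_ellipse_3d(transform_points(tf, ell2))
    expect_equal(fp$center, transform_points(tf, f0p$center),
                 tolerance = 1e-7)
    expect_equal(fp$semi_major, f0p$semi_major, tolerance = 1e-7)
    expect_equal(fp$semi_minor, f0p$semi_minor, tolerance = 1e-7)
  }
})
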