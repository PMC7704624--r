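# Mesh data model, mass properties, cutting, clipping, silhouettes.

test_that("cube mesh loads clean, closed, with analytic mass properties", {
  m <- make_cube()
  expect_equal(nrow(m$vertices), 8L)
  expect_true(m$closed)
  mp <- mass_properties(m)
  expect_equal(mp$volume, 1, tolerance = 1e-12)
  expect_equal(mp$center_of_mass, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(mp$inertia, diag(1 / 6, 3), tolerance = 1e-12)
  # translation equivariance: COM = t, inertia about COM unchanged
  mt <- make_cube(center = c(3, -2, 5))
  mpt <- mass_properties(mt)
  expect_equal(mpt$center_of_mass, c(3, -2, 5), tolerance = 1e-9)
  expect_equal(mpt$inertia, mp$inertia, tolerance = 1e-9)
})

test_that("open meshes are flagged and rejected by mass_properties", {
  m <- make_cube()
  open <- surface_mesh(m$vertices, m$faces[-1, , drop = FALSE])
  expect_false(open$closed)
  expect_error(mass_properties(open), "closed")
})

test_that("mesh volumes converge to analytic values", {
  # sphere: (4/3) pi r^3 within 0.5 % at moderate tessellation, converging
  s_fine <- make_sphere_mesh(r = 10, h = 0.5)
  s_coarse <- make_sphere_mesh(r = 10, h = 1.0)
  v_true <- 4 / 3 * pi * 1000
  err_fine <- abs(mass_properties(s_fine)$volume - v_true) / v_true
  err_coarse <- abs(mass_properties(s_coarse)$volume - v_true) / v_true
  expect_lt(err_fine, 0.005)
  expect_lt(err_fine, err_coarse)
  # capsule: pi r^2 L + 4/3 pi r^3
  cap <- make_implicit(function(p)
    femcoord:::sdf_capsule(p, c(0, 0, -15), c(0, 0, 15), 5),
    c(-8, -8, -23), c(8, 8, 23), 0.4)
  v_cap <- pi * 25 * 30 + 4 / 3 * pi * 125
  expect_lt(abs(mass_properties(cap)$volume - v_cap) / v_cap, 0.005)
})

test_that("plane cut of a cylinder gives one circular contour", {
  cap <- make_implicit(function(p)
    femcoord:::sdf_capsule(p, c(0, 0, -15), c(0, 0, 15), 5),
    c(-8, -8, -23), c(8, 8, 23), 0.4)
  ct <- cut_mesh_with_plane(cap, plane3(c(0, 0, 0), c(0, 0, 1)))
  expect_length(ct$components, 1)
  comp <- ct$components[[1]]
  expect_true(comp$closed)
  expect_equal(comp$perimeter, 2 * pi * 5, tolerance = 0.01)
  # contours are exactly planar
  expect_lt(max(abs(comp$points[, 3])), 1e-6)
})

test_that("plane cut misses and torus double-contour cases", {
  m <- make_cube()
  ct <- cut_mesh_with_plane(m, plane3(c(0, 0, 10), c(0, 0, 1)))
  expect_length(ct$components, 0)
  torus <- make_implicit(function(p) {
    sqrt((sqrt(p[, 1]^2 + p[, 2]^2) - 8)^2 + p[, 3]^2) - 3
  }, c(-13, -13, -5), c(13, 13, 5), 0.5)
  ct <- cut_mesh_with_plane(torus, plane3(c(0, 0, 0), c(1, 0, 0)))
  expect_length(ct$components, 2)
  expect_true(all(vapply(ct$components, `[[`, TRUE, "closed")))
  # independent oracle: every mesh edge crossing the plane contributes
  # exactly one deduplicated contour point
  s <- torus$vertices[, 1]
  e <- femcoord:::mesh_edges(torus)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), ]
  n_cross <- sum((s[e[, 1]] >= 0) != (s[e[, 2]] >= 0))
  n_pts <- sum(vapply(ct$components, function(c_) nrow(c_$points), 1L))
  expect_equal(n_pts, n_cross)
})

test_that("clipping splits faces exactly at the boundary", {
  m <- make_cube()
  half <- clip_mesh(m, plane3(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(range(half$vertices[, 1]), c(0, 0.5), tolerance = 1e-12)
  # volume oracle: signed tetra sum about an origin on the (planar) cut
  # boundary equals the clipped volume even though the mesh is open
  v <- half$vertices; f <- half$faces
  a <- v[f[, 1], ]; b <- v[f[, 2], ]; c_ <- v[f[, 3], ]
  w <- rowSums(a * cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                         b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                         b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  expect_equal(sum(w), 0.5, tolerance = 1e-9)
  # a ball containing the mesh is the identity
  same <- clip_mesh(m, list(center = c(0, 0, 0), radius = 10))
  expect_equal(nrow(same$faces), nrow(m$faces))
  expect_error(clip_mesh(m, plane3(c(0, 0, 10), c(0, 0, 1))), "removes")
})

test_that("clipping a femur to its middle half halves the extent", {
  mesh <- fx_coarse()$mesh
  d <- c(1, 0, 0)
  pr <- as.numeric(mesh$vertices %*% d)
  lo <- min(pr); span <- max(pr) - lo
  m1 <- clip_mesh(mesh, plane3(c(lo + 0.25 * span, 0, 0), d))
  m2 <- clip_mesh(m1, plane3(c(lo + 0.75 * span, 0, 0), -d))
  expect_equal(femcoord:::mesh_extent(m2, d), span / 2, tolerance = 1e-6)
})

test_that("silhouettes match analytic outlines", {
  s <- make_sphere_mesh(r = 10, h = 0.6)
  sil <- silhouette(s, c(0, 0, 1))
  expect_length(sil$components, 1)
  expect_equal(sil$components[[1]]$area, pi * 100, tolerance = 0.02 * pi * 100)
  cube <- make_cube()
  sc <- silhouette(cube, c(0, 0, 1), nbins = 400)
  expect_equal(sc$components[[1]]$area, 1, tolerance = 0.02)
  # two disjoint spheres: components reported; per-component area matches
  # the projected convex hull oracle
  two <- make_implicit(function(p)
    pmin(sqrt(rowSums(sweep(p, 2, c(-15, 0, 0))^2)) - 6,
         sqrt(rowSums(sweep(p, 2, c(15, 0, 0))^2)) - 6),
    c(-24, -9, -9), c(24, 9, 9), 0.6)
  st <- silhouette(two, c(0, 0, 1))
  expect_length(st$components, 2)
  comp_id <- femcoord:::mesh_vertex_components(two)
  for (ci in unique(comp_id)) {
    vv <- two$vertices[comp_id == ci, 1:2]
    hull <- vv[grDevices::chull(vv), ]
    n <- nrow(hull)
    hull_area <- abs(sum(hull[, 1] * hull[c(2:n, 1), 2] -
                         hull[c(2:n, 1), 1] * hull[, 2])) / 2
    areas <- vapply(st$components, `[[`, 0, "area")
    expect_true(any(abs(areas - hull_area) / hull_area < 0.02))
  }
  expect_error(silhouette(make_cube(half = c(0.5, 0.5, 1e-12)), c(1, 0, 0)),
               "degenerate")
})

test_that("mesh operations are equivariant under rigid transforms", {
  m <- fx_coarse()$mesh
  mp <- mass_properties(m)
  pl <- plane3(colMeans(m$vertices), c(0.3, 0.4, 0.86))
  ct <- cut_mesh_with_plane(m, pl)
  per0 <- sort(vapply(ct$components, `[[`, 0, "perimeter"))
  for (tf in random_transforms(4, seed = 42)) {
    mt <- transform_mesh(tf, m)
    mpt <- mass_properties(mt)
    expect_equal(mpt$volume, mp$volume, tolerance = 1e-9)
    expect_equal(mpt$center_of_mass,
                 transform_points(tf, mp$center_of_mass), tolerance = 1e-6)
    expect_equal(mpt$inertia,
                 tf$rotation %*% mp$inertia %*% t(tf$rotation),
                 tolerance = 1e-4)
    ctt <- cut_mesh_with_plane(mt, femcoord:::transform_plane(tf, pl))
    expect_equal(sort(vapply(ctt$components, `[[`, 0, "perimeter")), per0,
                 tolerance = 1e-9)
  }
})

test_that("rigid transforms compose, invert and validate", {
  tfs <- random_transforms(3, seed = 7)
  p <- matrix(rnorm(30), 10, 3)
  ab <- compose_transform(tfs[[1]], tfs[[2]])
  expect_equal(transform_points(ab, p),
               transform_points(tfs[[1]], transform_points(tfs[[2]], p)),
               tolerance = 1e-12)
  inv <- invert_transform(tfs[[1]])
  expect_equal(transform_points(inv, transform_points(tfs[[1]], p)), p,
               tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})
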