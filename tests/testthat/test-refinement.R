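# Stage 2 refinement operations, unit-tested on analytic solids and on
# the cached default synthetic femur (oracle = generator ground truth).

gt_in_reg <- function(what = c("landmarks", "axes", "planes")) {
  # transport the generator ground truth into registration space
  reg <- fx_reg()
  gt <- fx_default()$ground_truth
  Rt <- reg$transforms$prereg %*% reg$transforms$tfcs$rotation
  list(landmarks = reg$from_input(gt$landmarks),
       dirs = lapply(gt$axes, function(a) as.numeric(Rt %*% a$direction)),
       ttp_normal = as.numeric(Rt %*% gt$planes$TTP$normal))
}

test_that("head centre refinement matches the generator", {
  st <- fx_stages()
  gt <- gt_in_reg()
  s <- fx_reg()$transforms$scale
  expect_lt(femcoord:::vnorm(st$fh$fhc - gt$landmarks["FHC", ]), 0.5)
  expect_lt(abs(st$fh$radius / s - 24), 0.5)
  expect_true(st$fh$diagnostics$converged)
})

test_that("head refinement is exact on an ideal hemisphere patch", {
  set.seed(2)
  u <- matrix(rnorm(900), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u <- u[u[, 3] > -0.1, ]
  fh <- refine_fhc(sweep(u * 24, 2, c(1, 2, 3), "+"))
  expect_lt(femcoord:::vnorm(fh$fhc - c(1, 2, 3)), 1e-9)
  expect_equal(fh$radius, 24, tolerance = 1e-9)
})

test_that("a mis-mapped head region degrades the convergence flag", {
  st <- fx_stages()
  head_pts <- fx_reg()$mapped$regions$head
  shaft_pts <- fx_reg()$subject$vertices[
    abs(fx_reg()$subject$vertices[, 1]) < 40, , drop = FALSE]
  bad <- rbind(head_pts, shaft_pts[seq_len(nrow(head_pts) / 2), ])
  fh <- refine_fhc(bad)
  expect_false(fh$diagnostics$converged)
})

test_that("shaft axis detection works on an ideal offset-head cylinder", {
  mesh <- make_implicit(function(p) {
    pmin(femcoord:::sdf_capsule(p, c(0, 0, -150), c(0, 0, 150), 13),
         sqrt(rowSums(sweep(p, 2, c(40, 0, 175))^2)) - 24)
  }, c(-20, -20, -160), c(70, 28, 205), 2)
  res <- detect_shaft_axis(mesh, fhc = c(40, 0, 175))
  expect_lt(line_angle_deg(res$axis$direction, c(0, 0, 1)), 0.5)
  # orientation contract: directed proximally (toward the head-side end)
  com <- colMeans(mesh$vertices)
  expect_gt(sum(res$axis$direction * (c(40, 0, 175) - com)), 0)
})

test_that("shaft axis matches the generator ground truth", {
  st <- fx_stages()
  gt <- gt_in_reg()
  expect_lt(line_angle_deg(st$sh$axis$direction, gt$dirs$shaft), 2)
})

test_that("neck refinement finds the waist of an ideal cylinder", {
  r <- 13
  mesh <- make_implicit(function(p)
    femcoord:::sdf_capsule(p, c(0, 0, -40), c(0, 0, 40), r),
    c(-20, -20, -58), c(20, 20, 58), 1.2)
  # band shorter than r*sqrt(6), so its total-least-squares plane normal
  # is the cylinder axis (the initialization the stage expects)
  band <- mesh$vertices[abs(mesh$vertices[, 3]) < 12, , drop = FALSE]
  res <- refine_neck_axis(mesh, band, fhc = c(0, 0, 60))
  expect_equal(res$perimeter, 2 * pi * r, tolerance = 0.02 * 2 * pi * r)
  expect_lt(line_angle_deg(res$axis$direction, c(0, 0, 1)), 0.5)
  expect_gt(res$axis$direction[3], 0)  # directed toward the head
  # independence of the initial ellipse-normal sign (reversed point order
  # flips the fitted plane orientation)
  res2 <- refine_neck_axis(mesh, band[rev(seq_len(nrow(band))), ],
                           fhc = c(0, 0, 60))
  # agreement within the coordinate-descent resolution
  expect_lt(line_angle_deg(res$axis$direction, res2$axis$direction), 0.5)
})

test_that("neck axis matches the generator and decreases monotonically", {
  st <- fx_stages()
  gt <- gt_in_reg()
  expect_lt(line_angle_deg(st$nk$axis$direction, gt$dirs$neck), 2)
  expect_true(all(diff(st$nk$diagnostics$trace) < 0))
  expect_true(st$nk$diagnostics$converged)
})

test_that("table-top fixed point from the ground-truth pose is immediate", {
  fg <- fx_default()   # construction frame == ground-truth table-top pose
  gt <- fg$ground_truth
  v <- fg$mesh$vertices
  near <- function(lm) v[sqrt(rowSums(sweep(v, 2,
    gt$landmarks[lm, ])^2)) < 25, , drop = FALSE]
  regions <- list(medial_condyle = near("MPC"), lateral_condyle = near("LPC"))
  tp <- detect_ttp(fg$mesh, "right", gt$axes$neck, regions)
  expect_lte(tp$diagnostics$iterations, 2L)
  expect_true(tp$diagnostics$converged)
  # the three final landmarks are coplanar by construction
  d <- femcoord:::plane_signed_distance(tp$ttp, rbind(tp$lpc, tp$ptc))
  expect_lt(max(abs(d)), 1e-9)
  expect_lt(line_angle_deg(tp$ttp$normal, gt$planes$TTP$normal), 1)
})

test_that("table-top landmarks match the generator", {
  st <- fx_stages()
  gt <- gt_in_reg()
  s <- fx_reg()$transforms$scale
  for (nm in c("MPC", "LPC", "PTC")) {
    det <- switch(nm, MPC = st$tp$mpc, LPC = st$tp$lpc, PTC = st$tp$ptc)
    expect_lt(femcoord:::vnorm(det - gt$landmarks[nm, ]) / s, 1.5)
  }
  expect_lt(line_angle_deg(st$tp$ttp$normal, gt$ttp_normal), 1)
  expect_true(st$tp$diagnostics$converged)
})

test_that("sagittal-plane stage is exact on coaxial spheroid condyles", {
  rod <- function(p, yc) {
    yr <- p[, 2] - yc
    ycl <- pmin(9, pmax(-9, yr))
    w <- yr - ycl
    (sqrt((p[, 1] / 17)^2 + (w / 12)^2 + (p[, 3] / 22)^2) - 1) * 10
  }
  mesh <- make_implicit(function(p) pmin(rod(p, -22), rod(p, 22)),
                        c(-23, -50, -28), c(23, 50, 28), 1.5)
  v <- mesh$vertices
  # regions restricted to the cylindrical rod parts: every cut there is
  # the same exact ellipse, so the foci are exactly collinear and the
  # dispersion is tessellation noise only
  regions <- list(medial_condyle = v[v[, 2] > -31 & v[, 2] < -13, ],
                  lateral_condyle = v[v[, 2] > 13 & v[, 2] < 31, ])
  cm <- list(medial = femcoord:::submesh_by_vertices(mesh, v[, 2] < 0),
             lateral = femcoord:::submesh_by_vertices(mesh, v[, 2] > 0))
  us <- compute_usp(cm, regions, ml0 = c(0, 1, 0), post = c(0, 0, -1))
  expect_lt(line_angle_deg(us$pfea$direction, c(0, 1, 0)), 0.5)
  expect_lt(line_angle_deg(us$cea$direction, c(0, 1, 0)), 0.5)
  expect_lt(us$dispersion, 0.5)
})

test_that("a single sphere is rejected as a degenerate condyle pair", {
  s <- make_sphere_mesh(r = 20, h = 1.5)
  regions <- list(medial_condyle = s$vertices, lateral_condyle = s$vertices)
  cm <- list(medial = s, lateral = s)
  expect_error(compute_usp(cm, regions, c(0, 1, 0), c(0, 0, -1)),
               "distinct condyles")
})

test_that("centre axis matches the generator condylar axis", {
  st <- fx_stages()
  gt <- gt_in_reg()
  expect_lt(line_angle_deg(st$us$cea$direction, gt$dirs$condylar), 2)
  expect_true(all(diff(st$us$diagnostics$trace) < 0))
})

test_that("epicondyle candidates satisfy their contracts", {
  st <- fx_stages()
  gt <- gt_in_reg()
  s <- fx_reg()$transforms$scale
  # EC_CEA lies exactly on the surface
  for (side in c("medial", "lateral")) {
    cand <- st$ec$diagnostics[[side]]$candidates
    cp <- closest_point_on_mesh(st$distal, cand$ec_cea)
    expect_lt(cp$dist, 1e-6)
    expect_equal(st$ec$diagnostics[[side]]$branch, "ec_max")
  }
  expect_lt(femcoord:::vnorm(st$ec$mec - gt$landmarks["MEC", ]) / s, 2)
  expect_lt(femcoord:::vnorm(st$ec$lec - gt$landmarks["LEC", ]) / s, 2)
})

test_that("the notch is a boundary point close to the generator notch", {
  st <- fx_stages()
  gt <- gt_in_reg()
  s <- fx_reg()$transforms$scale
  # membership: the final notch is one of the computed boundary points
  hit <- apply(st$ic$boundary_points, 1, function(b)
    isTRUE(all.equal(as.numeric(b), as.numeric(st$ic$icn))))
  expect_true(any(hit))
  expect_lt(femcoord:::vnorm(st$ic$icn - gt$landmarks["ICN", ]) / s, 2)
})

test_that("deepening the groove moves the detected notch proximally", {
  xs <- vapply(c(6, 10), function(r) {
    fg <- generate_femur(femur_spec(notch_radius = r))
    res <- detect_anatomy(fg$mesh, "right", fx_template())
    res$landmarks["ICN", 1]
  }, 0)
  x_mid <- fx_default_result()$landmarks["ICN", 1]
  expect_true(xs[1] < x_mid && x_mid < xs[2])
})

test_that("mapped-only landmarks pass through with flags", {
  reg <- fx_reg()
  pt <- passthrough_landmarks(reg$mapped)
  expect_identical(pt$mapped_only, c("SGT", "LT"))
  # membership: the mapped SGT sits on the greater-trochanter bump
  lay <- femcoord:::femur_layout(femur_spec())
  gt_center_reg <- reg$from_input(matrix(lay$gt_center, 1, 3))
  expect_lt(femcoord:::vnorm(pt$sgt - gt_center_reg),
            (lay$gt_r + 3) * reg$transforms$scale)
  expect_error(passthrough_landmarks(list(landmarks = list())), "missing")
})

test_that("detected landmarks lie on the input surface (except FHC)", {
  res <- fx_default_result()
  mesh <- fx_default()$mesh
  on_surface <- res$landmarks[setdiff(rownames(res$landmarks), "FHC"), ]
  cp <- closest_point_on_mesh(mesh, on_surface)
  expect_lt(max(cp$dist), 1e-6)
  for (a in res$axes)
    expect_equal(femcoord:::vnorm(a$direction), 1, tolerance = 1e-9)
})
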