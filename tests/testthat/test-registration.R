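# Stage 1: TFCS alignment, pre-registration, LBS deformation, nonrigid
# ICP and anatomy mapping.

test_that("TFCS alignment recovers the principal axes of a box", {
  box <- make_cube(half = c(200, 20, 15))
  al <- align_to_tfcs(box)
  ext <- apply(al$mesh$vertices, 2, function(x) diff(range(x)))
  expect_equal(ext, c(400, 40, 30), tolerance = 1e-9)
  expect_lt(femcoord:::vnorm(colMeans(al$mesh$vertices)), 1e-9)
  # already-aligned input: rotation is an axis-sign-free identity
  al2 <- align_to_tfcs(al$mesh)
  expect_equal(abs(al2$transform$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # degenerate inertia (cube): ambiguity error
  expect_error(align_to_tfcs(make_cube()), "ambiguous|degenerate")
})

test_that("subjects are scaled to the template long-axis length", {
  tpl <- fx_template()
  short <- femcoord:::scale_mesh(tpl$mesh, 400 / 450)
  sc <- scale_to_template(short, tpl)
  expect_equal(sc$scale, 450 / 400, tolerance = 1e-12)
  expect_equal(femcoord:::mesh_extent(sc$mesh, c(1, 0, 0)),
               femcoord:::mesh_extent(tpl$mesh, c(1, 0, 0)),
               tolerance = 1e-9)
})

test_that("grid pre-registration resolves x-rotations and the y-flip", {
  tpl <- fx_template()
  # identity case: the zero rotation wins
  pre0 <- rough_preregister(tpl$mesh, tpl)
  expect_equal(pre0$diagnostics$psi %% 360, 0)
  expect_equal(pre0$diagnostics$flip, 0)
  # subject rotated about x: the recovered rotation undoes it within the
  # 5-degree refinement step
  R90 <- rotation_about(c(1, 0, 0), 90)
  rot <- tpl$mesh
  rot$vertices <- rot$vertices %*% t(R90)
  pre <- rough_preregister(rot, tpl)
  resid <- pre$rotation %*% R90
  ang <- acos((sum(diag(resid)) - 1) / 2) * 180 / pi
  expect_lt(ang, 5.1)
  # upside-down subject: the 180-degree y-flip branch is selected
  Rflip <- rotation_about(c(0, 1, 0), 180)
  flip <- tpl$mesh
  flip$vertices <- flip$vertices %*% t(Rflip)
  pref <- rough_preregister(flip, tpl)
  expect_equal(pref$diagnostics$flip, 180)
})

test_that("LBS deformation honours its parameters", {
  tpl <- fx_template()
  d0 <- deform_template(tpl, 0, 0, 0)
  expect_lt(max(abs(d0$mesh$vertices - tpl$mesh$vertices)), 1e-12)
  # commanded CCD change reflected exactly in the deformed rig axes
  for (dccd in c(-10, 7)) {
    d <- deform_template(tpl, 0, dccd, 0)
    ccd0 <- 180 - angle_between(tpl$rig$neck_dir, tpl$rig$shaft_dir)
    ccd1 <- 180 - angle_between(d$rig$neck_dir, d$rig$shaft_dir)
    expect_equal(ccd1 - ccd0, dccd, tolerance = 1e-9)
  }
  # neck elongation moves the head by the commanded length
  dn <- deform_template(tpl, 0, 0, 5)
  fhc0 <- tpl$rig$junction + tpl$rig$neck_length * tpl$rig$neck_dir
  fhc1 <- dn$rig$junction + dn$rig$neck_length * dn$rig$neck_dir
  expect_equal(femcoord:::vnorm(fhc1 - fhc0), 5, tolerance = 1e-9)
})

test_that("deformation fit compensates a version offset", {
  # subject generated at version 25 vs the template's 15.  The TFCS
  # alignment absorbs roughly half of the offset (the inertia axes twist
  # with version), so the fitted LBS offset is the sign-correct remainder
  # and alignment + deformation jointly line the neck up with the subject.
  fg <- fx_get("femur_v25", function()
    generate_femur(femur_spec(version_angle = 25)))
  al <- align_to_tfcs(fg$mesh)
  sc <- scale_to_template(al$mesh, fx_template())
  pre <- rough_preregister(sc$mesh, fx_template())
  subject <- sc$mesh
  subject$vertices <- subject$vertices %*% t(pre$rotation)
  fit <- fit_template_deformation(fx_template(), subject)
  expect_gt(fit$params[["dversion"]], 2)
  expect_lt(fit$params[["dversion"]], 13)
  Rt <- pre$rotation %*% al$transform$rotation
  gt_neck <- as.numeric(Rt %*% fg$ground_truth$axes$neck$direction)
  expect_lt(angle_between(fit$template$rig$neck_dir, gt_neck), 3.5)
})

test_that("nonrigid ICP has a fixed point at the template itself", {
  tpl <- fx_template()
  icp <- nonrigid_icp(tpl$mesh, tpl$mesh, steps = 4)
  expect_lt(icp$residuals[length(icp$residuals)], 1e-3)
  expect_lt(max(abs(icp$mesh$vertices - tpl$mesh$vertices)), 0.05)
})

test_that("nonrigid ICP recovers an anisotropic scaling", {
  tpl <- fx_template()
  target <- tpl$mesh
  target$vertices <- target$vertices %*% diag(c(1, 1.05, 0.95))
  icp <- nonrigid_icp(tpl$mesh, target)
  res <- icp$residuals
  expect_lt(res[length(res)], 0.5)
  expect_true(all(diff(res) < 1e-9))
})

test_that("anatomy mapping lands on the subject surface", {
  tpl <- fx_template()
  self <- map_anatomy(tpl$mesh, tpl, tpl$mesh)
  for (nm in names(tpl$landmarks))
    expect_equal(self$landmarks[[nm]],
                 tpl$mesh$vertices[tpl$landmarks[[nm]], ],
                 tolerance = 1e-9, ignore_attr = TRUE)
  reg <- fx_reg()
  fit <- fit_sphere(reg$mapped$regions$head)
  gt_fhc <- reg$from_input(fx_default()$ground_truth$landmarks["FHC", ])
  expect_lt(femcoord:::vnorm(fit$center - gt_fhc), 1)
  pts <- do.call(rbind, reg$mapped$landmarks)
  cp <- closest_point_on_mesh(reg$subject, pts)
  expect_lt(max(cp$dist), 1e-6)
})

test_that("registering the template to itself is identity-level", {
  tpl <- fx_template()
  reg <- fx_get("self_reg", function()
    register_template(tpl$mesh, "right", tpl))
  expect_equal(reg$transforms$scale, 1, tolerance = 1e-9)
  expect_lt(max(abs(reg$diagnostics$deformation$params)), 1)
  res <- reg$diagnostics$icp_residuals
  expect_lt(res[length(res)], 1e-2)
  for (nm in names(tpl$landmarks))
    expect_lt(femcoord:::vnorm(reg$mapped$landmarks[[nm]] -
                               tpl$mesh$vertices[tpl$landmarks[[nm]], ]), 1)
})
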