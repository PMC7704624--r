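# Bone coordinate frames and Euler-angle comparison.

test_that("Wu2002 frame matches the hand-computed example", {
  fr <- build_wu2002(fhc = c(0, 0, 400), mec = c(-40, 0, 0),
                     lec = c(40, 0, 0), side = "right")
  expect_equal(fr$axes["dp", ], c(0, 0, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(abs(fr$axes["ml", ]), c(1, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(abs(fr$axes["pa", ]), c(0, 1, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 0, 400))
  expect_error(build_wu2002(c(0, 0, 400), c(1, 2, 3), c(1, 2, 3), "right"),
               "degenerate")
})

test_that("Bergmann2016 uses the mutual perpendicular foot on the neck", {
  # orthogonal skew lines: the closest neck-axis point to the shaft axis
  # is (0, 0, 380), so with ICN at the origin the DP axis is +z
  neck <- line3(c(0, 50, 380), c(0, 1, 0))
  shaft <- line3(c(0, 0, 0), c(0, 0, 1))
  fr <- build_bergmann2016(fhc = c(5, 5, 400), mpc = c(-30, 0, -20),
                           lpc = c(30, 0, -20), icn = c(0, 0, 0),
                           neck_axis = neck, shaft_axis = shaft,
                           side = "right")
  expect_equal(fr$axes["dp", ], c(0, 0, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  # intersecting axes: the foot is the intersection point
  neck2 <- line3(c(0, 0, 380), c(0, 1, 0))
  fr2 <- build_bergmann2016(c(5, 5, 400), c(-30, 0, -20), c(30, 0, -20),
                            c(0, 0, 0), neck2, shaft, "right")
  expect_equal(fr2$axes["dp", ], c(0, 0, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(build_bergmann2016(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0),
                                  c(0, 0, -10), shaft, shaft, "right"),
               "parallel")
})

test_that("TableTop keeps the plane normal exact and re-orthogonalizes", {
  ttp <- plane3(c(0, 0, -30), c(0, 0.2, -0.98))  # realistic tilted normal
  fr <- build_tabletop(fhc = c(0, 0, 400), mpc = c(-30, 0, -30),
                       lpc = c(30, 2, -29), ttp = ttp, side = "right")
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-12)
  # 2nd axis (the plane normal) is kept exact, anterior-positive
  expect_equal(abs(sum(fr$axes["pa", ] * ttp$normal)), 1, tolerance = 1e-12)
  expect_gt(sum(fr$axes["pa", ] * (c(0, 0, 400) - c(0, 0, -30))), 0)
})

test_that("frames are equivariant under rigid transforms", {
  lm <- fx_default()$ground_truth$landmarks
  fr0 <- build_wu2002(lm["FHC", ], lm["MEC", ], lm["LEC", ], "right")
  for (tf in random_transforms(3, seed = 33)) {
    fr <- build_wu2002(transform_points(tf, lm["FHC", ]),
                       transform_points(tf, lm["MEC", ]),
                       transform_points(tf, lm["LEC", ]), "right")
    expect_equal(fr$axes, fr0$axes %*% t(tf$rotation), tolerance = 1e-9)
    expect_equal(fr$origin, transform_points(tf, lm["FHC", ]),
                 tolerance = 1e-9)
  }
})

test_that("mirrored femora give side-consistent frames", {
  gt_r <- fx_default()$ground_truth
  gt_l <- femcoord:::mirror_ground_truth(gt_r)
  lm_r <- gt_r$landmarks; lm_l <- gt_l$landmarks
  fr_r <- build_wu2002(lm_r["FHC", ], lm_r["MEC", ], lm_r["LEC", ], "right")
  fr_l <- build_wu2002(lm_l["FHC", ], lm_l["MEC", ], lm_l["LEC", ], "left")
  anterior <- c(0, 0, 1); proximal <- c(1, 0, 0)
  for (fr in list(fr_r, fr_l)) {
    expect_gt(sum(fr$axes["pa", ] * anterior), 0.9)
    expect_gt(sum(fr$axes["dp", ] * proximal), 0.9)
    expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  }
  # right-handedness forces ML lateral-positive on the right and
  # medial-positive on the left (documented convention)
  lateral_r <- c(0, 1, 0); lateral_l <- c(0, 1, 0) * -1
  expect_gt(sum(fr_r$axes["ml", ] * lateral_r), 0.9)
  expect_lt(sum(fr_l$axes["ml", ] * lateral_l), -0.9)
})

test_that("frame differences decompose and recompose exactly", {
  ref <- bone_frame("Wu2002", c(0, 0, 0), diag(3))
  expect_equal(unlist(frame_difference(ref, ref)[1:3]),
               c(adduction_abduction = 0, internal_external = 0,
                 flexion_extension = 0))
  # +5 degrees about the frame x-axis shows up as pure AA
  Rx <- rotation_about(c(1, 0, 0), 5)
  test <- bone_frame("Wu2002", c(0, 0, 0), t(Rx))
  d <- frame_difference(ref, test)
  expect_equal(d$adduction_abduction, 5, tolerance = 1e-9)
  expect_equal(d$internal_external, 0, tolerance = 1e-9)
  expect_equal(d$flexion_extension, 0, tolerance = 1e-9)
  # round trip to 1e-12 for a generic rotation
  R <- femcoord:::euler_xyz_to_matrix(17.3, -42.1, 131.9)
  eu <- femcoord:::matrix_to_euler_xyz(R)
  expect_equal(femcoord:::euler_xyz_to_matrix(eu$angles[1], eu$angles[2],
                                              eu$angles[3]),
               R, tolerance = 1e-12)
  # small-angle antisymmetry
  # antisymmetry is exact only to second order in the angles, so it is
  # checked deep inside the small-angle regime
  set.seed(13)
  for (i in 1:5) {
    Rs <- femcoord:::euler_xyz_to_matrix(runif(1, -0.005, 0.005),
                                         runif(1, -0.005, 0.005),
                                         runif(1, -0.005, 0.005))
    t2 <- bone_frame("Wu2002", c(0, 0, 0), t(Rs))
    ab <- unlist(frame_difference(ref, t2)[1:3])
    ba <- unlist(frame_difference(t2, ref)[1:3])
    expect_lt(max(abs(ab + ba)), 1e-6)
  }
})

test_that("the robustness harness honours identity and determinism", {
  mesh <- fx_coarse()$mesh
  idrep <- robustness_check(mesh, "right", fx_template(),
                            transforms = list(rigid_transform()))
  expect_identical(idrep$max_landmark_discrepancy, 0)
  expect_lt(idrep$max_frame_difference, 1e-12)
  r1 <- robustness_check(mesh, "right", fx_template(), n_transforms = 1,
                         seed = 5)
  r2 <- robustness_check(mesh, "right", fx_template(), n_transforms = 1,
                         seed = 5)
  expect_identical(r1$trials, r2$trials)
  expect_length(r1$failures, 0)
})
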