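# Parametric femur generator: construction identities, mirroring,
# determinism and template annotation.

test_that("default femur is closed and satisfies construction identities", {
  fg <- fx_default()
  gt <- fg$ground_truth
  expect_true(fg$mesh$closed)
  # neck-shaft angle identity (CCD measured between the neck direction
  # toward the head and the distally directed shaft axis)
  ccd <- 180 - angle_between(gt$axes$neck$direction,
                             gt$axes$shaft$direction)
  expect_equal(ccd, 125, tolerance = 1e-9)
  # FHC lies on the neck axis
  rel <- gt$landmarks["FHC", ] - gt$axes$neck$point
  perp <- rel - sum(rel * gt$axes$neck$direction) * gt$axes$neck$direction
  expect_lt(femcoord:::vnorm(perp), 1e-9)
  # MPC, LPC, PTC share the coordinate along the table-top normal
  d <- femcoord:::plane_signed_distance(gt$planes$TTP,
                                        gt$landmarks[c("MPC", "LPC", "PTC"), ])
  expect_lt(max(abs(d)), 1e-9)
})

test_that("version zero puts the neck in the shaft-condylar plane", {
  lay <- femcoord:::femur_layout(femur_spec(version_angle = 0))
  expect_lt(abs(lay$d_neck[3]), 1e-9)
})

test_that("left and right femora are exact mirror images", {
  spec_r <- femur_spec(tessellation = 3.2)
  spec_l <- femur_spec(side = "left", tessellation = 3.2)
  fr <- generate_femur(spec_r)
  fl <- generate_femur(spec_l)
  vr <- fr$mesh$vertices
  vr[, 2] <- -vr[, 2]
  expect_identical(fl$mesh$vertices, vr)
  lr <- fr$ground_truth$landmarks
  lr[, 2] <- -lr[, 2]
  expect_identical(fl$ground_truth$landmarks, lr)
})

test_that("generation is deterministic", {
  a <- generate_femur(fx_coarse_spec())
  b <- fx_coarse()
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(femur_spec(ccd_angle = 80), "ccd_angle")
  expect_error(femur_spec(version_angle = 75), "version_angle")
  expect_error(femur_spec(total_length = -1), "positive")
})

test_that("ground-truth notch moves proximally as the carve deepens", {
  xs <- vapply(c(6, 8, 10), function(r) {
    spec <- femur_spec(notch_radius = r)
    gt <- femcoord:::compute_ground_truth(spec,
                                          femcoord:::femur_layout(spec))
    gt$landmarks["ICN", 1]
  }, 0)
  expect_true(all(diff(xs) > 0))
})

test_that("template annotation is consistent with the ground truth", {
  tpl <- fx_template()
  gt <- tpl$ground_truth
  # head region sphere-fit centre close to the generator FHC
  fit <- fit_sphere(tpl$mesh$vertices[tpl$regions$head, ])
  expect_lt(femcoord:::vnorm(fit$center - gt$landmarks["FHC", ]), 0.2)
  # regions disjoint where anatomy is disjoint
  expect_length(intersect(tpl$regions$head, tpl$regions$medial_condyle), 0)
  expect_length(intersect(tpl$regions$medial_condyle,
                          tpl$regions$lateral_condyle), 0)
  # TFCS alignment: principal long axis along x, centre of mass at origin
  mp <- mass_properties(tpl$mesh)
  expect_lt(femcoord:::vnorm(mp$center_of_mass), 1e-6)
  ee <- eigen(mp$inertia, symmetric = TRUE)
  expect_lt(line_angle_deg(ee$vectors[, 3], c(1, 0, 0)), 1)
  ext <- apply(tpl$mesh$vertices, 2, function(x) diff(range(x)))
  expect_equal(unname(which.max(ext)), 1L)
  # required annotation names are present
  expect_true(all(c("MEC_map", "LEC_map", "SGT", "LT", "PTC_seed") %in%
                  names(tpl$landmarks)))
})

test_that("template serialization round-trips through PLY + JSON", {
  tpl <- fx_template()
  path <- tempfile()
  save_template(tpl, path)
  back <- load_template(path)
  expect_equal(nrow(back$mesh$vertices), nrow(tpl$mesh$vertices))
  expect_identical(unlist(back$landmarks), unlist(tpl$landmarks))
  expect_identical(lapply(back$regions, as.integer),
                   lapply(tpl$regions, as.integer))
  expect_equal(back$rig$neck_dir, tpl$rig$neck_dir, tolerance = 1e-9)
  unlink(paste0(path, c(".ply", ".json")))
})
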