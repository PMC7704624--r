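# Stage 1: single-atlas registration.
#
# The subject is aligned to its principal axes of inertia (TFCS), scaled to
# the template length, pre-registered on a coarse rotation grid, matched by
# a two-bone linear-blend-skinning deformation of the template (version,
# CCD angle, neck length), and finally registered with a nonrigid ICP with
# per-vertex affine transforms and a decreasing stiffness schedule.
# Landmarks and regions ride along on the template vertices and are mapped
# to the closest subject surface points.

#' Align a mesh to its principal axes of inertia (TFCS)
#'
#' The output mesh has its centre of mass at the origin and its principal
#' axes along the coordinate axes, x being the smallest-inertia (long)
#' axis, z the largest.  Axis signs are canonical (largest magnitude
#' component positive) but anatomically arbitrary; the anatomical
#' orientation of Table-2 type (x proximal, z anterior) is recovered later
#' by the grid pre-registration.
#'
#' @param mesh A closed `surface_mesh`.
#' @return List with `mesh` (aligned) and `transform` (the
#'   `rigid_transform` mapping input to output coordinates).
#' @export
align_to_tfcs <- function(mesh) {
  mp <- mass_properties(mesh)
  ee <- eigen(mp$inertia, symmetric = TRUE)
  gaps <- abs(diff(ee$values)) / max(abs(ee$values))
  if (any(gaps < 1e-9))
    stop("ambiguous principal axes: inertia tensor is (near) degenerate")
  x_axis <- ee$vectors[, 3]
  z_axis <- ee$vectors[, 1]
  for (ax in c("x", "z")) {
    a <- if (ax == "x") x_axis else z_axis
    k <- which.max(abs(a))
    if (a[k] < 0) a <- -a
    if (ax == "x") x_axis <- a else z_axis <- a
  }
  y_axis <- cross3(z_axis, x_axis)
  R <- rbind(x_axis, y_axis, z_axis)
  dimnames(R) <- NULL
  tf <- rigid_transform(R, as.numeric(-R %*% mp$center_of_mass))
  list(mesh = transform_mesh(tf, mesh), transform = tf)
}

#' Scale a subject to the template length
#'
#' Isotropic scaling so that the subject's extent along the TFCS long axis
#' (x) equals the template's.
#'
#' @param subject TFCS-aligned subject `surface_mesh`.
#' @param template An `atlas_template` (TFCS-aligned by construction).
#' @return List with `mesh` (scaled subject) and `scale` (factor applied).
#' @export
scale_to_template <- function(subject, template) {
  es <- mesh_extent(subject, c(1, 0, 0))
  et <- mesh_extent(template$mesh, c(1, 0, 0))
  if (es < 1e-9) stop("subject has zero extent along the long axis")
  s <- et / es
  list(mesh = scale_mesh(subject, s), scale = s)
}

# deterministic vertex subsample (every k-th vertex)
subsample_idx <- function(n, target) {
  if (n <= target) return(seq_len(n))
  seq(1, n, by = ceiling(n / target))
}

#' Grid pre-registration of a subject to the template
#'
#' Scores candidate rotations of the subject about the TFCS long axis
#' (10 degree grid), with and without a 180 degree flip about y (upside
#' down case), by the sum of template-to-subject nearest-neighbour
#' distances; then refines the x-rotation on a 5 degree grid scored on the
#' distal part only (to line up the condyles).
#'
#' @param subject TFCS-aligned, scaled subject `surface_mesh`.
#' @param template An `atlas_template`.
#' @return List with `rotation` (3x3, to apply to the subject), `score`,
#'   and the two grid score tables in `diagnostics`.
#' @export
rough_preregister <- function(subject, template) {
  tv <- template$mesh$vertices
  sv <- subject$vertices
  tsub <- tv[subsample_idx(nrow(tv), 1200), , drop = FALSE]
  ssub <- sv[subsample_idx(nrow(sv), 2500), , drop = FALSE]
  score_grid <- expand.grid(psi = seq(0, 350, by = 10), flip = c(0, 180))
  scores <- numeric(nrow(score_grid))
  for (i in seq_len(nrow(score_grid))) {
    R <- rotation_about(c(1, 0, 0), score_grid$psi[i]) %*%
      rotation_about(c(0, 1, 0), score_grid$flip[i])
    scores[i] <- cpp_nn_sumdist(tsub, ssub %*% t(R))
  }
  best <- which.min(scores)
  psi0 <- score_grid$psi[best]
  flip <- score_grid$flip[best]
  # distal refinement: 5 degree grid, scored on the distal 40 % only
  xr <- range(tv[, 1])
  distal_t <- tv[tv[, 1] < xr[1] + 0.4 * diff(xr), , drop = FALSE]
  distal_t <- distal_t[subsample_idx(nrow(distal_t), 1600), , drop = FALSE]
  Rflip <- rotation_about(c(0, 1, 0), flip)
  sflip <- sv[subsample_idx(nrow(sv), 6000), , drop = FALSE] %*% t(Rflip)
  # x-rotations do not move points along x, so the distal subject subset
  # is fixed once the flip is resolved
  sd <- sflip[sflip[, 1] < xr[1] + 0.45 * diff(xr), , drop = FALSE]
  if (nrow(sd) == 0) sd <- sflip
  psis <- seq(0, 355, by = 5)
  dscore <- numeric(length(psis))
  for (i in seq_along(psis)) {
    R <- rotation_about(c(1, 0, 0), psis[i])
    dscore[i] <- cpp_nn_sumdist(distal_t, sd %*% t(R)) / nrow(distal_t)
  }
  psi <- psis[which.min(dscore)]
  R <- rotation_about(c(1, 0, 0), psi) %*% Rflip
  list(rotation = R, score = min(dscore),
       diagnostics = list(coarse = cbind(score_grid, score = scores),
                          fine = data.frame(psi = psis, score = dscore),
                          psi = psi, flip = flip))
}

# --------------------------------------------------------------------------
# Linear blend skinning deformation (two-bone rig: shaft + neck)
# --------------------------------------------------------------------------

# per-vertex skinning weight: smoothstep ramp along the neck axis
lbs_weights <- function(template) {
  rig <- template$rig
  t_neck <- as.numeric(sweep(template$mesh$vertices, 2, rig$junction) %*%
                       rig$neck_dir)
  smoothstep((t_neck - 5) / 15)
}

#' Deform a template by version / CCD / neck-length offsets
#'
#' Two-bone linear blend skinning: the neck-head assembly rotates about the
#' neck-shaft junction (CCD tilt within the neck-shaft plane, version about
#' the shaft axis) and stretches along the neck; shaft vertices stay put,
#' with a smoothstep weight ramp across the junction.  Landmarks and
#' regions ride along by vertex index.
#'
#' @param template An `atlas_template`.
#' @param dversion Version offset, degrees.
#' @param dccd CCD angle offset, degrees.
#' @param dneck Neck length offset, mm.
#' @return The deformed `atlas_template` (rig updated accordingly).
#' @export
deform_template <- function(template, dversion = 0, dccd = 0, dneck = 0) {
  rig <- template$rig
  w <- lbs_weights(template)
  ccd_axis <- cross3(rig$shaft_dir, rig$neck_dir)
  if (vnorm(ccd_axis) < 1e-9)
    stop("degenerate rig: neck parallel to shaft")
  # increasing CCD opens the neck toward the shaft axis; increasing
  # version rotates the neck anteriorly, which is a rotation about the
  # negative shaft axis on a right femur and the positive one on a left
  vaxis <- rig$shaft_dir * if (identical(template$side, "right")) -1 else 1
  M <- rotation_about(vaxis, dversion) %*%
    rotation_about(ccd_axis, -dccd)
  v <- template$mesh$vertices
  rel <- sweep(v, 2, rig$junction)
  vrot <- rel %*% t(M)
  new_neck_dir <- as.numeric(M %*% rig$neck_dir)
  t_neck <- pmin(1, pmax(0, (rel %*% rig$neck_dir) / rig$neck_length))
  target <- sweep(vrot + (t_neck * dneck) %*% t(new_neck_dir),
                  2, rig$junction, "+")
  template$mesh$vertices <- v + w * (target - v)
  template$rig$neck_dir <- new_neck_dir
  template$rig$neck_length <- rig$neck_length + dneck
  template$rig$ccd <- rig$ccd + dccd
  template$rig$version <- rig$version + dversion
  if (!is.null(template$ground_truth)) {
    gt <- template$ground_truth
    gt$axes$neck <- line3(rig$junction, new_neck_dir)
    gt$landmarks["FHC", ] <- rig$junction +
      (rig$neck_length + dneck) * new_neck_dir
    template$ground_truth <- gt
  }
  template
}

#' Fit the template deformation parameters to a subject
#'
#' Coarse grid search (version within 20 degrees in 5 degree steps, CCD
#' within 15 degrees in 5 degree steps, neck length within 10 percent in
#' 5 percent steps) followed by Nelder-Mead refinement, scored by the mean
#' nearest-neighbour distance of the proximal template part to the subject.
#'
#' @param template An `atlas_template`.
#' @param subject Pre-registered, scaled subject `surface_mesh`.
#' @return List with `template` (deformed), `params`
#'   (dversion, dccd, dneck) and `score`.
#' @export
fit_template_deformation <- function(template, subject) {
  tv <- template$mesh$vertices
  xr <- range(tv[, 1])
  prox_sel <- which(tv[, 1] > xr[1] + 0.55 * diff(xr))
  prox_sel <- prox_sel[subsample_idx(length(prox_sel), 800)]
  sv <- subject$vertices
  ssub <- sv[sv[, 1] > xr[1] + 0.5 * diff(xr), , drop = FALSE]
  ssub <- ssub[subsample_idx(nrow(ssub), 2500), , drop = FALSE]
  w <- lbs_weights(template)
  nl <- template$rig$neck_length
  score <- function(p) {
    # penalty keeps Nelder-Mead inside the rig bounds
    pen <- sum(pmax(0, abs(p) - c(20, 15, 0.10 * nl))^2)
    d <- deform_template(template, p[1], p[2], p[3])
    cpp_nn_sumdist(d$mesh$vertices[prox_sel, , drop = FALSE], ssub) /
      length(prox_sel) + pen
  }
  grid <- expand.grid(dversion = seq(-20, 20, by = 5),
                      dccd = seq(-15, 15, by = 5),
                      dneck = seq(-0.10, 0.10, by = 0.05) * nl)
  gs <- apply(as.matrix(grid), 1, score)
  p0 <- as.numeric(grid[which.min(gs), ])
  opt <- stats::optim(p0, score, method = "Nelder-Mead",
                      control = list(maxit = 120, reltol = 1e-4))
  p <- pmin(c(20, 15, 0.10 * nl), pmax(-c(20, 15, 0.10 * nl), opt$par))
  list(template = deform_template(template, p[1], p[2], p[3]),
       params = c(dversion = p[1], dccd = p[2], dneck = p[3]),
       score = opt$value)
}

# --------------------------------------------------------------------------
# Nonrigid ICP (per-vertex affine, stiffness-regularized)
# --------------------------------------------------------------------------

#' Nonrigid iterative closest point registration
#'
#' Locally affine registration in the spirit of Amberg et al.: each
#' template vertex carries a 3x4 affine transform; the objective balances
#' the distance of transformed vertices to their closest points on the
#' subject surface against a stiffness term penalizing transform
#' differences across template edges.  The stiffness decreases over a
#' geometric schedule; each stiffness level is solved by alternating
#' closest-point lookup with a sparse linear solve.
#'
#' @param template_mesh Template `surface_mesh` (pre-registered, deformed).
#' @param subject Subject `surface_mesh` in the same space.
#' @param stiffness Initial stiffness weight.
#' @param steps Number of stiffness levels.
#' @param factor Geometric decay of the stiffness per level.
#' @param inner Closest-point/solve alternations per level.
#' @param gamma Weight of the translation column in the stiffness metric.
#' @return List with `mesh` (deformed template, same topology),
#'   `residuals` (mean closest-point distance after each level) and
#'   `converged` (logical).
#' @export
nonrigid_icp <- function(template_mesh, subject, stiffness = 100,
                         steps = 8, factor = 0.7, inner = 2, gamma = 1) {
  v <- template_mesh$vertices
  n <- nrow(v)
  e <- mesh_edges(template_mesh)
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(ekey), , drop = FALSE]
  ne <- nrow(e)
  # stiffness matrix M kron G: 4 rows per edge
  gvals <- c(1, 1, 1, gamma)
  MG <- Matrix::sparseMatrix(
    i = rep(seq_len(4 * ne), 2),
    j = c(as.vector(vapply(1:4, function(k) (e[, 1] - 1) * 4 + k,
                           numeric(ne))),
          as.vector(vapply(1:4, function(k) (e[, 2] - 1) * 4 + k,
                           numeric(ne)))),
    x = c(rep(gvals, each = ne), rep(-gvals, each = ne)),
    dims = c(4 * ne, 4 * n))
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 4),
    j = c((seq_len(n) - 1) * 4 + 1, (seq_len(n) - 1) * 4 + 2,
          (seq_len(n) - 1) * 4 + 3, (seq_len(n) - 1) * 4 + 4),
    x = c(v[, 1], v[, 2], v[, 3], rep(1, n)),
    dims = c(n, 4 * n))
  MGtMG <- Matrix::crossprod(MG)
  DtD <- Matrix::crossprod(D)
  # identity initialization
  X <- matrix(0, 4 * n, 3)
  X[(seq_len(n) - 1) * 4 + 1, 1] <- 1
  X[(seq_len(n) - 1) * 4 + 2, 2] <- 1
  X[(seq_len(n) - 1) * 4 + 3, 3] <- 1
  residuals <- numeric(0)
  alpha <- stiffness
  cp <- cpp_closest_on_mesh(v, subject$vertices, subject$faces)
  for (s in seq_len(steps)) {
    AtA <- alpha^2 * MGtMG + DtD
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(AtA), LDL = FALSE)
    for (it in seq_len(inner)) {
      X <- as.matrix(Matrix::solve(ch, Matrix::crossprod(D, cp$point)))
      vdef <- as.matrix(D %*% X)
      cp <- cpp_closest_on_mesh(vdef, subject$vertices, subject$faces)
    }
    residuals <- c(residuals, mean(cp$dist))
    alpha <- alpha * factor
  }
  out <- template_mesh
  out$vertices <- as.matrix(D %*% X)
  list(mesh = out, residuals = residuals,
       converged = residuals[length(residuals)] < 1.0)
}

# --------------------------------------------------------------------------
# Mapping
# --------------------------------------------------------------------------

#' Map template landmarks and regions onto the subject surface
#'
#' Landmarks are mapped to their closest points on the subject surface.
#' Regions are transferred by Voronoi assignment: every subject vertex
#' joins the region of its nearest deformed-template vertex (if that
#' vertex is labelled), so mapped regions are dense at the subject's own
#' resolution rather than sampled at the template's.
#'
#' @param deformed_mesh Deformed template `surface_mesh` in subject space.
#' @param template The `atlas_template` carrying the annotation indices.
#' @param subject Subject `surface_mesh`.
#' @return List with `landmarks` (named list of 3-vectors), `regions`
#'   (named list of Nx3 matrices of subject vertex positions),
#'   `region_indices` (subject vertex indices) and `mapping_dist`
#'   diagnostics.
#' @export
map_anatomy <- function(deformed_mesh, template, subject) {
  v <- deformed_mesh$vertices
  lm_idx <- unlist(template$landmarks)
  lm_cp <- cpp_closest_on_mesh(v[lm_idx, , drop = FALSE],
                               subject$vertices, subject$faces)
  landmarks <- stats::setNames(
    lapply(seq_along(lm_idx), function(i) as.numeric(lm_cp$point[i, ])),
    names(template$landmarks))
  nn <- cpp_nn(subject$vertices, v)
  region_indices <- lapply(template$regions, function(idx) {
    which(nn$index %in% idx)
  })
  regions <- lapply(region_indices, function(si)
    subject$vertices[si, , drop = FALSE])
  for (nm in names(regions))
    if (nrow(regions[[nm]]) == 0) stop("empty mapped region: ", nm)
  list(landmarks = landmarks, regions = regions,
       region_indices = region_indices,
       mapping_dist = list(landmarks = lm_cp$dist,
                           vertex_assignment = nn$dist))
}

# --------------------------------------------------------------------------
# Stage-1 orchestration
# --------------------------------------------------------------------------

#' Run the full atlas registration stage
#'
#' TFCS alignment, scaling, grid pre-registration, template deformation
#' fit and nonrigid ICP, followed by landmark/region mapping.  All results
#' are expressed in the registration space (subject TFCS-aligned, scaled
#' and grid-rotated); `to_input` maps registration-space points back to
#' the input mesh coordinates.
#'
#' @param mesh Subject `surface_mesh` (closed, full femur).
#' @param side `"left"` or `"right"`.
#' @param template An `atlas_template` (its side is adapted by mirroring).
#' @param config See [femcoord_config()].
#' @return List with `subject` (registration-space mesh), `mapped`,
#'   `deformed_template`, `transforms` (`tfcs`, `scale`, `prereg`),
#'   `to_input`/`from_input` (closures for points) and `diagnostics`.
#' @export
register_template <- function(mesh, side, template = default_template(),
                              config = femcoord_config()) {
  if (!isTRUE(mesh$closed)) stop("registration requires a closed mesh")
  if (!identical(template$side, side)) template <- mirror_template(template)
  al <- align_to_tfcs(mesh)
  sc <- scale_to_template(al$mesh, template)
  pre <- rough_preregister(sc$mesh, template)
  subject <- sc$mesh
  subject$vertices <- subject$vertices %*% t(pre$rotation)
  fit <- fit_template_deformation(template, subject)
  icp <- nonrigid_icp(fit$template$mesh, subject,
                      stiffness = config$icp_stiffness,
                      steps = config$icp_steps,
                      factor = config$icp_factor,
                      inner = config$icp_inner)
  mapped <- map_anatomy(icp$mesh, fit$template, subject)
  R_total <- pre$rotation %*% al$transform$rotation
  s <- sc$scale
  t_total <- as.numeric(pre$rotation %*% al$transform$translation) * s
  to_input <- function(pts) {
    single <- is.null(dim(pts))
    if (single) pts <- matrix(pts, 1, 3)
    out <- sweep(pts, 2, t_total) %*% R_total / s
    if (single) as.numeric(out) else out
  }
  from_input <- function(pts) {
    single <- is.null(dim(pts))
    if (single) pts <- matrix(pts, 1, 3)
    out <- sweep(s * pts %*% t(R_total), 2, t_total, "+")
    if (single) as.numeric(out) else out
  }
  list(subject = subject, mapped = mapped,
       deformed_template = list(mesh = icp$mesh, template = fit$template),
       transforms = list(tfcs = al$transform, scale = s,
                         prereg = pre$rotation),
       to_input = to_input, from_input = from_input,
       diagnostics = list(prereg = pre$diagnostics,
                          deformation = fit[c("params", "score")],
                          icp_residuals = icp$residuals,
                          icp_converged = icp$converged))
}
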