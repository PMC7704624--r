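# Atlas template: a synthetic femur mesh annotated with named landmark
# vertices and named vertex regions, pre-aligned to the temporary femoral
# coordinate system (TFCS: origin at the centre of mass, x distal(-)/
# proximal(+), y medial(-)/lateral(+), z posterior(-)/anterior(+) for a
# right femur).

#' Atlas template constructor
#'
#' @param mesh TFCS-aligned `surface_mesh`.
#' @param landmarks Named list of single vertex indices.
#' @param regions Named list of vertex index vectors.
#' @param rig Two-bone skinning rig parameters (junction, shaft/neck
#'   directions, neck length) used by [deform_template()].
#' @param ground_truth Optional generator ground truth in template frame.
#' @param side `"left"` or `"right"`.
#' @param spec The generating `femur_spec`, if any.
#' @return Object of class `atlas_template`.
#' @export
atlas_template <- function(mesh, landmarks, regions, rig,
                           ground_truth = NULL, side = "right", spec = NULL) {
  required_landmarks <- c("MEC_map", "LEC_map", "SGT", "LT", "PTC_seed")
  required_regions <- c("head", "neck", "medial_condyle", "lateral_condyle")
  missing <- setdiff(required_landmarks, names(landmarks))
  if (length(missing)) stop("missing template landmarks: ",
                            paste(missing, collapse = ", "))
  missing <- setdiff(required_regions, names(regions))
  if (length(missing)) stop("missing template regions: ",
                            paste(missing, collapse = ", "))
  nv <- nrow(mesh$vertices)
  idx <- c(unlist(landmarks), unlist(regions))
  if (any(idx < 1 | idx > nv)) stop("template vertex index out of range")
  if (any(vapply(regions, length, 1L) == 0))
    stop("empty template region")
  structure(list(mesh = mesh, landmarks = landmarks, regions = regions,
                 rig = rig, ground_truth = ground_truth, side = side,
                 spec = spec),
            class = "atlas_template")
}

#' @export
print.atlas_template <- function(x, ...) {
  cat(sprintf("<atlas_template> %s femur, %d vertices\n", x$side,
              nrow(x$mesh$vertices)))
  cat("landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  cat("regions:", paste(sprintf("%s(%d)", names(x$regions),
                                vapply(x$regions, length, 1L)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Generate the annotated atlas template
#'
#' Builds a synthetic femur for `spec`, aligns it to the TFCS (principal
#' axes of inertia, signs resolved with the generator ground truth) and
#' annotates landmark vertices and vertex regions from the construction
#' geometry.
#'
#' @param spec A `femur_spec`; the packaged default template uses
#'   `femur_spec(tessellation = 3.5)`.
#' @return An `atlas_template`.
#' @export
generate_template <- function(spec = femur_spec(tessellation = 3.5)) {
  fg <- generate_femur(spec)
  mesh <- fg$mesh
  gt <- fg$ground_truth
  lay <- femur_layout(spec)
  ms <- if (spec$side == "left") -1 else 1  # construction-frame y mirror
  # --- exact TFCS alignment, signs resolved from ground truth ------------
  mp <- mass_properties(mesh)
  ee <- eigen(mp$inertia, symmetric = TRUE)  # values descending
  x_axis <- ee$vectors[, 3]                  # smallest inertia = long axis
  if (sum(x_axis * (gt$landmarks["FHC", ] - mp$center_of_mass)) < 0)
    x_axis <- -x_axis
  z_axis <- ee$vectors[, 1]
  if (sum(z_axis * (-gt$planes$TTP$normal)) < 0)  # anterior positive
    z_axis <- -z_axis
  y_axis <- cross3(z_axis, x_axis)
  R <- rbind(x_axis, y_axis, z_axis)
  dimnames(R) <- NULL
  tf <- rigid_transform(R, as.numeric(-R %*% mp$center_of_mass))
  mesh <- transform_mesh(tf, mesh)
  gt <- transform_ground_truth(tf, gt)
  v <- mesh$vertices
  # --- annotation (in construction frame, then transported) --------------
  cons <- function(pts) {  # template-frame -> construction frame
    pts <- transform_points(invert_transform(tf), pts)
    pts[, 2] <- ms * pts[, 2]
    pts
  }
  vc <- cons(v)
  near_vertex <- function(p_cons) {
    p <- matrix(p_cons, 1, 3)
    p[, 2] <- ms * p[, 2]
    p <- transform_points(tf, p)
    cpp_nn(p, v)$index
  }
  # landmark vertices: nearest mesh vertex to the construction-frame point
  map_dir_m <- unitize(c(0.8, -0.55, 1.0))
  map_dir_l <- unitize(c(0.8, 0.55, 1.0))
  lm_pts <- list(
    FHC_seed = lay$junction + spec$neck_length * lay$d_neck,
    MEC_map = lay$epi_m + lay$epi_r * map_dir_m,
    LEC_map = lay$epi_l + lay$epi_r * map_dir_l,
    SGT = lay$gt_center + c(lay$gt_r, 0, 0),
    LT = lay$lt_center + lay$lt_r *
      unitize(c(0, lay$lt_center[2],
                lay$lt_center[3] - shaft_midline_z(spec, lay,
                                                   lay$lt_center[1]))),
    PTC_seed = c(lay$crest_p1[1], lay$crest_p1[2], lay$z_table))
  landmarks <- lapply(lm_pts, near_vertex)
  # regions from construction geometry
  fhc_c <- lay$junction + spec$neck_length * lay$d_neck
  d_head <- sqrt(rowSums(sweep(vc, 2, fhc_c)^2))
  head_idx <- which(d_head <= 1.05 * spec$head_radius)
  t_neck <- as.numeric(sweep(vc, 2, lay$junction) %*% lay$d_neck)
  rad_neck <- sqrt(pmax(rowSums(sweep(vc, 2, lay$junction)^2) - t_neck^2, 0))
  neck_idx <- which(t_neck >= 0.35 * spec$neck_length &
                    t_neck <= 0.80 * spec$neck_length &
                    rad_neck < 2.0 * lay$neck_radius)
  cond_idx <- function(rod) {
    which(abs(sdf_condyle_rod(vc, rod)) < 1.2)
  }
  regions <- list(head = head_idx, neck = neck_idx,
                  medial_condyle = cond_idx(lay$cond_m),
                  lateral_condyle = cond_idx(lay$cond_l))
  if (any(vapply(regions, length, 1L) == 0))
    stop("generation error: empty region at this tessellation")
  rig <- list(junction = as.numeric(transform_points(
                tf, matrix(c(lay$junction[1], ms * lay$junction[2],
                             lay$junction[3]), 1, 3))),
              shaft_dir = as.numeric(transform_directions(
                tf, matrix(c(1, 0, 0), 1, 3))),
              neck_dir = as.numeric(transform_directions(
                tf, matrix(c(lay$d_neck[1], ms * lay$d_neck[2],
                             lay$d_neck[3]), 1, 3))),
              neck_length = spec$neck_length,
              ccd = spec$ccd_angle, version = spec$version_angle)
  atlas_template(mesh, landmarks, regions, rig, ground_truth = gt,
                 side = spec$side, spec = spec)
}

# mirror a template about the TFCS x-z plane (used when subject side and
# template side differ); medial/lateral region names keep their anatomical
# meaning
mirror_template <- function(tpl) {
  tpl$mesh <- mirror_mesh(tpl$mesh, axis = 2)
  if (!is.null(tpl$ground_truth))
    tpl$ground_truth <- mirror_ground_truth(tpl$ground_truth)
  tpl$rig$junction[2] <- -tpl$rig$junction[2]
  tpl$rig$shaft_dir[2] <- -tpl$rig$shaft_dir[2]
  tpl$rig$neck_dir[2] <- -tpl$rig$neck_dir[2]
  tpl$side <- if (tpl$side == "left") "right" else "left"
  tpl
}

# --------------------------------------------------------------------------
# Serialization: PLY mesh + JSON sidecar (schema version 1)
# --------------------------------------------------------------------------

#' Save an atlas template
#'
#' Writes `<path>.ply` (mesh) and `<path>.json` (sidecar with landmarks,
#' regions, rig and schema version; vertex indices are 1-based).
#'
#' @param tpl An `atlas_template`.
#' @param path Output path prefix (without extension).
#' @return `path`, invisibly.
#' @export
save_template <- function(tpl, path) {
  write_mesh(tpl$mesh, paste0(path, ".ply"))
  sidecar <- list(schema = "femcoord-template-v1",
                  side = tpl$side,
                  landmarks = tpl$landmarks,
                  regions = tpl$regions,
                  rig = tpl$rig)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an atlas template written by [save_template()]
#' @param path Path prefix used at save time.
#' @return An `atlas_template`.
#' @export
load_template <- function(path) {
  mesh <- load_mesh(paste0(path, ".ply"))
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(sc$schema, "femcoord-template-v1"))
    stop("unsupported template schema: ", sc$schema)
  atlas_template(mesh, as.list(sc$landmarks), as.list(sc$regions),
                 rig = sc$rig, side = sc$side)
}

# packaged default template, built once per session
template_cache <- new.env(parent = emptyenv())

#' The packaged default atlas template
#'
#' A right-side synthetic template at 3.5 mm tessellation, generated on
#' first use and cached for the session.
#'
#' @return An `atlas_template`.
#' @export
default_template <- function() {
  if (is.null(template_cache$tpl))
    template_cache$tpl <- generate_template()
  template_cache$tpl
}
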