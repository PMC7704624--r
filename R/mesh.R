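# Indexed triangle mesh data model.  Vertices are Nx3 (mm), faces Mx3
# 1-based vertex indices with counter-clockwise outward orientation.

#' Triangular surface mesh
#'
#' Constructs a cleaned surface mesh: duplicate vertices within `tol` mm are
#' merged and zero-area faces are dropped.  Units are fixed to millimetres by
#' contract; no unit inference is attempted (STL carries no units).
#'
#' @param vertices Nx3 numeric matrix of vertex coordinates (mm).
#' @param faces Mx3 integer matrix of 1-based vertex indices,
#'   counter-clockwise seen from outside.
#' @param clean Merge duplicate vertices and drop degenerate faces.
#' @param tol Vertex merge tolerance in mm.
#' @return Object of class `surface_mesh` with fields `vertices`, `faces`,
#'   `closed` (logical: every edge shared by exactly two faces) and
#'   `units = "mm"`.
#' @export
surface_mesh <- function(vertices, faces, clean = TRUE, tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("vertices and faces must have 3 columns")
  if (nrow(vertices) == 0 || nrow(faces) == 0)
    stop("empty mesh")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (clean) {
    m <- merge_vertices(vertices, faces, tol)
    vertices <- m$vertices
    faces <- m$faces
    faces <- drop_degenerate_faces(vertices, faces)
    if (nrow(faces) == 0) stop("mesh has no non-degenerate faces")
    used <- sort(unique(as.vector(faces)))
    if (length(used) < nrow(vertices)) {
      remap <- integer(nrow(vertices))
      remap[used] <- seq_along(used)
      vertices <- vertices[used, , drop = FALSE]
      faces <- matrix(remap[faces], ncol = 3)
    }
  }
  mesh <- structure(list(vertices = vertices, faces = faces, units = "mm"),
                    class = "surface_mesh")
  mesh$closed <- is_closed_mesh(mesh)
  mesh
}

merge_vertices <- function(vertices, faces, tol) {
  # quantized-key merge; exact duplicates from facet-soup writers collapse
  key <- apply(round(vertices / max(tol, 1e-12)), 1, paste, collapse = ",")
  first <- !duplicated(key)
  # vertices[first, ] lists the unique vertices in first-occurrence order,
  # so the unique-key index is the new vertex index directly
  remap <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3))
}

# Topological cleaning only: faces whose corners collapsed onto a shared
# vertex (the way zero-area facets appear in facet-soup files after the
# vertex merge) are dropped.  This is parity-safe, so a closed input stays
# closed; zero-area faces with three distinct vertices are left alone.
drop_degenerate_faces <- function(vertices, faces) {
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  faces[keep, , drop = FALSE]
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
}

#' Test whether every edge is shared by exactly two faces
#' @param mesh A `surface_mesh`.
#' @return Logical scalar.
#' @export
is_closed_mesh <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, %s [mm]\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#' @param tf A `rigid_transform`.
#' @param mesh A `surface_mesh`.
#' @return Transformed mesh (topology unchanged).
#' @export
transform_mesh <- function(tf, mesh) {
  mesh$vertices <- transform_points(tf, mesh$vertices)
  mesh
}

scale_mesh <- function(mesh, s) {
  mesh$vertices <- mesh$vertices * s
  mesh
}

# mirror a mesh about a coordinate plane (axis = 1, 2 or 3), fixing the
# face winding so normals stay outward
mirror_mesh <- function(mesh, axis = 2) {
  mesh$vertices[, axis] <- -mesh$vertices[, axis]
  mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

mesh_extent <- function(mesh, direction) {
  d <- unitize(direction)
  proj <- as.numeric(mesh$vertices %*% d)
  max(proj) - min(proj)
}

#' Volume, center of mass and inertia tensor of a closed mesh
#'
#' Divergence-theorem accumulation over signed tetrahedra spanned by the
#' origin and each face (unit density).  The inertia tensor is reported
#' about the center of mass.
#'
#' @param mesh A closed `surface_mesh`.
#' @return List with `volume` (mm^3), `center_of_mass` (3-vector, mm) and
#'   `inertia` (symmetric 3x3, about the center of mass).
#' @export
mass_properties <- function(mesh) {
  if (!isTRUE(mesh$closed))
    stop("mass_properties requires a closed mesh")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # signed volume of tetra (origin, a, b, c)
  cxb <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
               b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
               b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  w <- rowSums(a * cxb) / 6
  volume <- sum(w)
  if (volume <= 0) stop("non-positive volume: faces are not oriented outward")
  com <- colSums(w * (a + b + c_) / 4) / volume
  # second moments via canonical tetra quadrature:
  # integral over tetra of x_i x_j = 6V/120 * (sum_k sum_l p_ki p_lj + sum_k p_ki p_kj)
  sxx <- syy <- szz <- sxy <- sxz <- syz <- 0
  P <- list(a, b, c_)
  s1 <- a + b + c_  # vertex sums (origin contributes zero)
  f2 <- function(i, j) {
    acc <- s1[, i] * s1[, j]
    for (p in P) acc <- acc + p[, i] * p[, j]
    sum(w / 20 * acc)
  }
  sxx <- f2(1, 1); syy <- f2(2, 2); szz <- f2(3, 3)
  sxy <- f2(1, 2); sxz <- f2(1, 3); syz <- f2(2, 3)
  # shift second moments to the center of mass
  sxx <- sxx - volume * com[1]^2
  syy <- syy - volume * com[2]^2
  szz <- szz - volume * com[3]^2
  sxy <- sxy - volume * com[1] * com[2]
  sxz <- sxz - volume * com[1] * com[3]
  syz <- syz - volume * com[2] * com[3]
  inertia <- matrix(c(syy + szz, -sxy, -sxz,
                      -sxy, sxx + szz, -syz,
                      -sxz, -syz, sxx + syy), 3, 3)
  list(volume = volume, center_of_mass = com, inertia = inertia)
}

# vertex connected components; returns integer component id per vertex
mesh_vertex_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  e <- mesh_edges(mesh)
  for (k in seq_len(nrow(e))) {
    ra <- find(e[k, 1]); rb <- find(e[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# sub-mesh on a vertex subset (faces with all three vertices kept)
submesh_by_vertices <- function(mesh, keep) {
  if (is.logical(keep)) keep <- which(keep)
  if (length(keep) == 0) stop("empty vertex selection")
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  fkeep <- rowSums(matrix(mesh$faces %in% keep, ncol = 3)) == 3
  faces <- matrix(remap[mesh$faces[fkeep, , drop = FALSE]], ncol = 3)
  if (nrow(faces) == 0) stop("vertex selection keeps no complete face")
  mesh <- structure(list(vertices = mesh$vertices[keep, , drop = FALSE],
                         faces = faces, units = "mm"),
                    class = "surface_mesh")
  mesh$closed <- is_closed_mesh(mesh)
  mesh
}

#' Closest points on a mesh surface
#'
#' @param mesh A `surface_mesh`.
#' @param pts Nx3 matrix (or 3-vector) of query points.
#' @return List with `point` (Nx3 closest surface points), `dist` and `face`.
#' @export
closest_point_on_mesh <- function(mesh, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  cpp_closest_on_mesh(pts, mesh$vertices, mesh$faces)
}
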