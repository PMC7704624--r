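# Planar cross-sections, half-space / ball clipping with exact face
# splitting, and orthographic silhouettes.

#' Planar contour container
#'
#' Ordered (closed or open) polylines lying in a common plane, with
#' per-component perimeter and enclosed area.  Produced by
#' [cut_mesh_with_plane()] and [silhouette()].
#'
#' @param plane The `plane3` containing the contour.
#' @param components List of lists with fields `points` (Kx3, ordered,
#'   first vertex not repeated), `closed`, `perimeter`, `area`.
#' @return Object of class `planar_contour`.
#' @export
planar_contour <- function(plane, components) {
  structure(list(plane = plane, components = components),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour> %d component(s)\n", length(x$components)))
  for (comp in x$components)
    cat(sprintf("  %d points, %s, perimeter %.3f mm, area %.3f mm^2\n",
                nrow(comp$points), if (comp$closed) "closed" else "open",
                comp$perimeter, comp$area))
  invisible(x)
}

contour_metrics <- function(points, closed, plane) {
  b <- plane_basis(plane$normal)
  rel <- sweep(points, 2, plane$point)
  u <- as.numeric(rel %*% b$u)
  v <- as.numeric(rel %*% b$v)
  n <- length(u)
  if (closed) {
    nxt <- c(2:n, 1)
  } else {
    nxt <- c(2:n, n)
  }
  perim <- sum(sqrt((u[nxt] - u)^2 + (v[nxt] - v)^2))
  area <- if (closed) abs(sum(u * v[nxt] - u[nxt] * v)) / 2 else 0
  list(perimeter = perim, area = area)
}

#' Cross-section of a mesh with a plane
#'
#' Intersects every face with the plane and chains the resulting segments
#' into polylines.  On a closed mesh every component is a closed loop.  The
#' returned points are projected exactly onto the plane.
#'
#' @param mesh A `surface_mesh`.
#' @param plane A `plane3`.
#' @return A `planar_contour`; zero components when the plane misses the
#'   mesh.
#' @export
cut_mesh_with_plane <- function(mesh, plane) {
  comps <- cpp_plane_cut(mesh$vertices, mesh$faces, plane$point, plane$normal)
  out <- lapply(comps, function(comp) {
    pts <- comp$points
    # snap exactly onto the plane
    d <- plane_signed_distance(plane, pts)
    pts <- pts - outer(d, plane$normal)
    m <- contour_metrics(pts, comp$closed, plane)
    list(points = pts, closed = comp$closed,
         perimeter = m$perimeter, area = m$area)
  })
  planar_contour(plane, out)
}

# --------------------------------------------------------------------------
# Clipping
# --------------------------------------------------------------------------

#' Clip a mesh to a half-space or a ball
#'
#' Faces crossing the region boundary are split at the boundary (linearly
#' along edges), so extreme-point queries after clipping are not quantized
#' to the input tessellation.  For a `plane3` region the kept side is the
#' normal side; for a ball the kept side is the inside.  The curved ball
#' boundary is approximated by edge chords.
#'
#' @param mesh A `surface_mesh`.
#' @param region Either a `plane3` (keep the normal side) or a list
#'   `list(center =, radius =)` (keep the inside of the ball).
#' @return The clipped (possibly open) `surface_mesh`.
#' @export
clip_mesh <- function(mesh, region) {
  v <- mesh$vertices
  if (inherits(region, "plane3")) {
    s <- plane_signed_distance(region, v)
    tfun <- function(a, b) s[a] / (s[a] - s[b])
  } else if (is.list(region) && !is.null(region$center)) {
    d <- sweep(v, 2, region$center)
    s <- region$radius - sqrt(rowSums(d^2))  # >= 0 inside the ball
    tfun <- function(a, b) {
      # chord crossing of the sphere along edge a->b
      p <- v[a, ]; q <- v[b, ]
      dd <- q - p
      pc <- p - region$center
      A <- sum(dd^2); B <- 2 * sum(pc * dd); C <- sum(pc^2) - region$radius^2
      disc <- max(B^2 - 4 * A * C, 0)
      roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      roots <- roots[roots >= -1e-9 & roots <= 1 + 1e-9]
      if (length(roots) == 0) 0.5 else min(max(roots[1], 0), 1)
    }
  } else stop("region must be a plane3 or list(center=, radius=)")
  keep <- s >= 0
  f <- mesh$faces
  nk <- keep[f[, 1]] + keep[f[, 2]] + keep[f[, 3]]
  full <- f[nk == 3L, , drop = FALSE]
  cross_idx <- which(nk == 1L | nk == 2L)
  new_v <- list()
  new_f <- list()
  edge_cache <- new.env(parent = emptyenv())
  nv0 <- nrow(v)
  split_edge <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    tt <- if (a < b) tfun(a, b) else 1 - tfun(b, a)
    p <- v[a, ] + tt * (v[b, ] - v[a, ])
    new_v[[length(new_v) + 1L]] <<- p
    id <- nv0 + length(new_v)
    edge_cache[[key]] <- id
    id
  }
  for (i in cross_idx) {
    tri <- f[i, ]
    k <- keep[tri]
    # rotate so the pattern starts at a kept vertex
    rot <- if (sum(k) == 1L) which(k) else which(!k)
    ord <- ((rot - 1 + 0:2) %% 3) + 1
    a <- tri[ord[1]]; b <- tri[ord[2]]; c_ <- tri[ord[3]]
    if (sum(k) == 1L) {
      pab <- split_edge(a, b)
      pca <- split_edge(c_, a)
      new_f[[length(new_f) + 1L]] <- c(a, pab, pca)
    } else {
      # a dropped, b and c kept
      pab <- split_edge(a, b)
      pca <- split_edge(c_, a)
      new_f[[length(new_f) + 1L]] <- c(pab, b, c_)
      new_f[[length(new_f) + 1L]] <- c(pab, c_, pca)
    }
  }
  allv <- rbind(v, do.call(rbind, new_v))
  allf <- rbind(full, do.call(rbind, new_f))
  if (is.null(allf) || nrow(allf) == 0) stop("clip region removes everything")
  surface_mesh(allv, allf)
}

# --------------------------------------------------------------------------
# Silhouette
# --------------------------------------------------------------------------

# scanline envelope of the orthographic projection of a mesh along `normal`:
# per bin midpoint of the v-coordinate, the [min, max] of u over all
# triangle crossings.  Shared by silhouette() and the notch detector.
silhouette_envelope <- function(mesh, u_axis, v_axis, nbins = 256) {
  pu <- as.numeric(mesh$vertices %*% u_axis)
  pv <- as.numeric(mesh$vertices %*% v_axis)
  e <- mesh_edges(mesh)
  va <- pv[e[, 1]]; vb <- pv[e[, 2]]
  ua <- pu[e[, 1]]; ub <- pu[e[, 2]]
  vmin <- min(pv); vmax <- max(pv)
  mids <- seq(vmin, vmax, length.out = nbins + 2)[2:(nbins + 1)]
  lo <- numeric(nbins); hi <- numeric(nbins); ok <- logical(nbins)
  for (i in seq_len(nbins)) {
    v0 <- mids[i]
    crossing <- (va - v0) * (vb - v0) <= 0 & va != vb
    if (!any(crossing)) next
    tt <- (v0 - va[crossing]) / (vb[crossing] - va[crossing])
    uu <- ua[crossing] + tt * (ub[crossing] - ua[crossing])
    lo[i] <- min(uu); hi[i] <- max(uu); ok[i] <- TRUE
  }
  list(v = mids[ok], lo = lo[ok], hi = hi[ok])
}

#' Orthographic silhouette outline of a mesh
#'
#' Projects the mesh along `view_direction` and extracts the outline of the
#' projection per connected mesh component, as a scanline envelope (the
#' outline is exact for shapes whose projection is monotone along the
#' scanline axis, which covers the convex solids and condyle sectors used
#' here; components are reported separately, not merged).
#'
#' @param mesh A `surface_mesh`.
#' @param view_direction Unit 3-vector; the projection plane passes through
#'   the mesh centroid.
#' @param nbins Number of scanlines.
#' @return A `planar_contour` in the projection plane with one closed
#'   component per connected mesh component.
#' @export
silhouette <- function(mesh, view_direction, nbins = 256) {
  n <- unitize(view_direction)
  b <- plane_basis(n)
  ctr <- colMeans(mesh$vertices)
  plane <- plane3(ctr, n)
  span_u <- diff(range(mesh$vertices %*% b$u))
  span_v <- diff(range(mesh$vertices %*% b$v))
  if (span_u < 1e-9 || span_v < 1e-9)
    stop("degenerate silhouette: mesh is flat along the view direction")
  comp_id <- mesh_vertex_components(mesh)
  comps <- lapply(unique(comp_id), function(ci) {
    sub <- submesh_by_vertices(mesh, comp_id == ci)
    env <- silhouette_envelope(sub, b$u, b$v, nbins)
    # closed polygon: lower chain then upper chain reversed
    u2 <- c(env$lo, rev(env$hi))
    v2 <- c(env$v, rev(env$v))
    # (u, v) are absolute coordinates along bu, bv through the origin
    pts <- outer(u2, b$u) + outer(v2, b$v) + outer(rep(sum(ctr * n), length(u2)), n)
    m <- contour_metrics(pts, TRUE, plane)
    list(points = pts, closed = TRUE, perimeter = m$perimeter, area = m$area)
  })
  planar_contour(plane, comps)
}
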