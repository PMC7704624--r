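# Stage 2: a-priori-knowledge refinement of landmarks, axes and planes.
# All stages operate in the registration space (x distal(-)/proximal(+),
# z posterior(-)/anterior(+), template side matched to the subject) and
# are transported back to input coordinates by the orchestrator.

#' Refine the femoral head centre
#'
#' Least-squares sphere fit to the mapped head vertices.
#'
#' @param head_points Nx3 matrix of mapped head surface points (N >= 50).
#' @return List with `fhc`, `radius` and `diagnostics` (residuals,
#'   `converged` flag degraded when the fit residual exceeds 1 mm).
#' @export
refine_fhc <- function(head_points) {
  if (nrow(head_points) < 50)
    stop("head region too small for a stable sphere fit")
  fit <- fit_sphere(head_points)
  list(fhc = fit$center, radius = fit$radius,
       diagnostics = list(rms_residual = fit$rms_residual,
                          rms_algebraic = fit$rms_algebraic,
                          n_points = nrow(head_points),
                          converged = fit$rms_residual <= 1.0))
}

#' Detect the shaft axis
#'
#' The two mesh vertices at maximal pairwise distance define the bone's
#' diameter direction (oriented proximally using the head centre); the
#' proximal and distal quarters along it are resected and an ellipsoid is
#' fitted to the remaining mid-shaft, whose major axis is the shaft axis.
#'
#' @param mesh Subject `surface_mesh`.
#' @param fhc Femoral head centre (3-vector).
#' @return List with `axis` (`line3`, directed proximally) and
#'   `diagnostics`.
#' @export
detect_shaft_axis <- function(mesh, fhc) {
  v <- mesh$vertices
  sub <- subsample_idx(nrow(v), 6000)
  pair <- cpp_max_pair(v[sub, , drop = FALSE])
  p1 <- v[sub[pair[1]], ]; p2 <- v[sub[pair[2]], ]
  d <- unitize(p2 - p1)
  mid <- (p1 + p2) / 2
  if (sum(d * (fhc - mid)) < 0) d <- -d
  len <- sum((p2 - p1) * d)
  base <- if (sum(d * (p2 - p1)) > 0) p1 else p2
  lo <- clip_mesh(mesh, plane3(base + 0.25 * abs(len) * d, d))
  midm <- clip_mesh(lo, plane3(base + 0.75 * abs(len) * d, -d))
  fit <- fit_ellipsoid(midm$vertices)
  axis_dir <- fit$axes[, 1]
  if (sum(axis_dir * d) < 0) axis_dir <- -axis_dir
  list(axis = line3(fit$center, axis_dir),
       diagnostics = list(diameter = abs(len), radii = fit$radii,
                          rms_residual = fit$rms_residual))
}

# contour component whose centroid is nearest to a line; closed loops only
select_contour_near_line <- function(contour, line) {
  best <- NULL; bestd <- Inf
  for (comp in contour$components) {
    if (!comp$closed || nrow(comp$points) < 8) next
    ctr <- colMeans(comp$points)
    rel <- ctr - line$point
    dd <- vnorm(rel - sum(rel * line$direction) * line$direction)
    if (dd < bestd) { bestd <- dd; best <- comp }
  }
  best
}

#' Refine the neck axis by minimal-perimeter cuts
#'
#' Starts from the normal of an ellipse fitted to the mapped neck region
#' and iteratively reorients/offsets a cutting plane through the neck
#' (coordinate descent on two tilt angles with a shrinking step, nested
#' offset line search) until the perimeter of the neck-containing cutting
#' contour converges to a minimum.  The axis through the centroid of the
#' minimal contour, directed toward the head centre, is returned.
#'
#' @param mesh Subject `surface_mesh`.
#' @param neck_points Mapped neck region surface points.
#' @param fhc Head centre (orients the axis).
#' @param config See [femcoord_config()].
#' @return List with `axis` (`line3`), `perimeter`, `diagnostics`
#'   (objective trace, iterations, `converged`).
#' @export
refine_neck_axis <- function(mesh, neck_points, fhc,
                             config = femcoord_config()) {
  if (nrow(neck_points) < 6) stop("neck region too small")
  ell <- fit_ellipse_3d(neck_points)
  d <- ell$normal
  if (sum(d * (fhc - ell$center)) < 0) d <- -d
  anchor <- ell$center
  toff <- as.numeric(sweep(neck_points, 2, anchor) %*% d)
  # restrict the cuts to a tube around the initial axis; far-away
  # structures crossed by the extended plane are irrelevant and costly
  rel <- sweep(mesh$vertices, 2, anchor)
  tax <- as.numeric(rel %*% d)
  rad <- sqrt(pmax(rowSums(rel^2) - tax^2, 0))
  tube <- tax > min(toff) - 15 & tax < max(toff) + 15 & rad < 45
  neck_mesh <- submesh_by_vertices(mesh, tube)
  perim_at <- function(d, t) {
    axis <- line3(anchor, d)
    ct <- cut_mesh_with_plane(neck_mesh, plane3(anchor + t * d, d))
    comp <- select_contour_near_line(ct, axis)
    if (is.null(comp)) Inf else comp$perimeter
  }
  best_offset <- function(d) {
    # the admissible offsets follow the neck region along the *current*
    # direction (the mapped band can sit skewed w.r.t. the initial
    # normal, and the waist must stay reachable)
    tcur <- as.numeric(sweep(neck_points, 2, anchor) %*% d)
    off_range <- stats::quantile(tcur, c(0.05, 0.95), names = FALSE) +
      c(-4, 4)
    ts <- seq(off_range[1], off_range[2], length.out = 9)
    ps <- vapply(ts, function(t) perim_at(d, t), 0)
    i <- which.min(ps)
    if (!is.finite(ps[i])) return(c(ts[1], Inf))
    # golden-section refinement around the grid minimum
    lo <- ts[max(1, i - 1)]; hi <- ts[min(length(ts), i + 1)]
    opt <- stats::optimize(function(t) perim_at(d, t), c(lo, hi),
                           tol = 1e-3)
    if (opt$objective < ps[i]) c(opt$minimum, opt$objective)
    else c(ts[i], ps[i])
  }
  cur <- best_offset(d)
  trace <- cur[2]
  step <- config$neck_step_init
  iter <- 0
  while (step >= config$neck_step_min && iter < config$neck_max_iter) {
    improved <- FALSE
    b <- plane_basis(d)
    for (axis_vec in list(b$u, b$v)) {
      for (sgn in c(1, -1)) {
        iter <- iter + 1
        d_try <- as.numeric(rotation_about(axis_vec, sgn * step) %*% d)
        cand <- best_offset(d_try)
        if (cand[2] < cur[2] - config$neck_tol) {
          d <- d_try; cur <- cand
          trace <- c(trace, cur[2])
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) step <- step / 2
  }
  ct <- cut_mesh_with_plane(neck_mesh, plane3(anchor + cur[1] * d, d))
  comp <- select_contour_near_line(ct, line3(anchor, d))
  if (is.null(comp)) stop("no neck-containing cutting contour found")
  ctr <- colMeans(comp$points)
  if (sum(d * (fhc - ctr)) < 0) d <- -d
  list(axis = line3(ctr, d), perimeter = cur[2],
       diagnostics = list(trace = trace, iterations = iter,
                          init_normal = ell$normal,
                          converged = iter < config$neck_max_iter))
}

#' Detect the table-top plane and its three contact points
#'
#' Fixed-point iteration: in the current frame, take the most posterior
#' point of the medial condyle, the lateral condyle and the proximal part
#' (head resected at the neck to guard against retroversion); the three
#' points define a new table-top plane whose normal becomes the posterior
#' direction of the next iterate; stop when the frame update rotation is
#' within tolerance of the identity.
#'
#' @param mesh Subject `surface_mesh`.
#' @param side `"left"` or `"right"` (labels only; parts carry the side).
#' @param neck_axis `line3` of the refined neck axis.
#' @param regions Mapped regions (`medial_condyle`, `lateral_condyle`).
#' @param config See [femcoord_config()].
#' @return List with `mpc`, `lpc`, `ptc`, `ttp` (`plane3`, normal directed
#'   posteriorly) and `diagnostics` (iterations, final update angle,
#'   `converged`).
#' @export
detect_ttp <- function(mesh, side, neck_axis, regions,
                       config = femcoord_config()) {
  v <- mesh$vertices
  xmax <- max(v[, 1])
  prox <- v[v[, 1] > 0.3 * xmax, , drop = FALSE]
  head_side <- as.numeric(sweep(prox, 2, neck_axis$point) %*%
                          neck_axis$direction)
  prox <- prox[head_side <= 0, , drop = FALSE]
  if (nrow(prox) == 0) stop("neck resection removed the proximal part")
  parts <- list(medial = regions$medial_condyle,
                lateral = regions$lateral_condyle,
                proximal = prox)
  post <- c(0, 0, -1)
  angle <- Inf
  it <- 0
  while (it < config$ttp_max_iter) {
    it <- it + 1
    pts <- t(vapply(parts, function(p) {
      p[which.max(p %*% post), ]
    }, c(0, 0, 0)))
    n <- cross3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
    if (vnorm(n) < 1e-9) stop("degenerate table-top contact points")
    n <- unitize(n)
    if (sum(n * post) < 0) n <- -n
    angle <- acos(max(-1, min(1, sum(n * post))))
    post <- n
    if (angle < config$ttp_tol) break
  }
  list(mpc = pts["medial", ], lpc = pts["lateral", ], ptc = pts["proximal", ],
       ttp = plane3(pts["medial", ], post),
       diagnostics = list(iterations = it, last_update_rad = angle,
                          converged = angle < config$ttp_tol))
}

# uniform arc-length resampling of a closed polyline
resample_closed <- function(pts, step = 1.5) {
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[c(2:n, 1), ] - pts)^2))
  total <- sum(seg)
  m <- max(24, round(total / step))
  s_cum <- c(0, cumsum(seg))
  targets <- seq(0, total, length.out = m + 1)[1:m]
  idx <- findInterval(targets, s_cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (targets - s_cum[idx]) / pmax(seg[idx], 1e-12)
  pts[idx, , drop = FALSE] +
    (pts[c(2:n, 1), , drop = FALSE][idx, , drop = FALSE] -
     pts[idx, , drop = FALSE]) * frac
}

# stack of parallel cutting planes across a condyle region; returns ellipse
# fits of the articulating (posterior-distal) contour arcs
condyle_stack_fit <- function(cond_mesh, region_pts, d_ml, post, dist,
                              n_planes, arc_margin_deg) {
  ctr <- colMeans(region_pts)
  t_r <- as.numeric(sweep(region_pts, 2, ctr) %*% d_ml)
  # quantile-based stack placement is robust to mapping outliers at the
  # region rims (e.g. osteophytes picked up by the label transfer)
  rng <- stats::quantile(t_r, c(0.15, 0.85), names = FALSE)
  ts <- seq(rng[1], rng[2], length.out = n_planes)
  centers <- NULL; foci <- NULL
  for (t in ts) {
    p0 <- ctr + t * d_ml
    ct <- cut_mesh_with_plane(cond_mesh, plane3(p0, d_ml))
    comp <- select_contour_near_line(ct, line3(ctr, d_ml))
    if (is.null(comp)) next
    pts <- comp$points
    # the articulating arc is taken in a condyle-anchored frame: angles
    # about the region centroid (close to the condyle axis), not about the
    # contour centroid, which is biased by the trochlea and shaft
    c0 <- ctr + sum((colMeans(pts) - ctr) * d_ml) * d_ml
    rel <- sweep(pts, 2, c0)
    u <- as.numeric(rel %*% post)   # posterior positive
    w <- as.numeric(rel %*% dist)   # distal positive
    ang <- atan2(w, u) * 180 / pi   # 0 = posterior, 90 = distal
    keep <- ang > -arc_margin_deg & ang < 90 + arc_margin_deg
    if (sum(keep) < 8) next
    fit <- tryCatch(fit_ellipse_3d(pts[keep, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pf <- fit$foci[which.max(fit$foci %*% post), ]
    centers <- rbind(centers, fit$center)
    foci <- rbind(foci, pf)
  }
  list(centers = centers, foci = foci)
}

#' Unified sagittal plane, posterior focal elliptic axis and centre axis
#'
#' Iterates the orientation of a stack of sagittal cutting planes through
#' each condyle; per cut, an ellipse is fitted to the articulating
#' (posterior-distal) arc of the condyle contour; the objective is the
#' dispersion (sum of squared distances) of the posterior ellipse foci
#' about their best-fit line.  At the minimizing orientation the PFEA is
#' the line through the posterior foci, the CEA the line through the
#' ellipse centres, and the USP the plane normal to the cutting direction
#' through the mean focus.
#'
#' @param condyle_meshes List with `medial` and `lateral` condyle
#'   sub-meshes (cutting them instead of the whole distal part keeps the
#'   contours clean and fast).
#' @param regions Mapped condyle regions (point matrices).
#' @param ml0 Initial mediolateral direction (posterior condylar axis,
#'   lateral positive).
#' @param post Posterior direction (table-top normal).
#' @param config See [femcoord_config()].
#' @return List with `usp` (`plane3`), `pfea`, `cea` (`line3`, lateral
#'   positive), `dispersion` and `diagnostics` (trace, `converged`).
#' @export
compute_usp <- function(condyle_meshes, regions, ml0, post,
                        config = femcoord_config()) {
  dist_dir <- unitize(cross3(ml0, post) *
                      sign(sum(cross3(ml0, post) * c(-1, 0, 0))))
  sep <- sum((colMeans(regions$lateral_condyle) -
              colMeans(regions$medial_condyle)) * ml0)
  if (sep < 10)
    stop("degenerate distal geometry: two distinct condyles are required")
  objective <- function(d_ml) {
    fits <- lapply(list(
      list(m = condyle_meshes$medial, r = regions$medial_condyle),
      list(m = condyle_meshes$lateral, r = regions$lateral_condyle)),
                   function(cm) condyle_stack_fit(
                     cm$m, cm$r, d_ml, post, dist_dir,
                     config$usp_planes, config$usp_arc_margin))
    foci <- do.call(rbind, lapply(fits, `[[`, "foci"))
    centers <- do.call(rbind, lapply(fits, `[[`, "centers"))
    if (is.null(foci) || nrow(foci) < 4 ||
        any(vapply(fits, function(f) is.null(f$foci) || nrow(f$foci) < 2,
                   TRUE)))
      return(list(value = Inf))
    fl <- fit_line_tls(foci)
    rel <- sweep(foci, 2, fl$point)
    perp <- rel - (rel %*% fl$direction) %*% t(fl$direction)
    list(value = sum(perp^2), foci = foci, centers = centers, line = fl)
  }
  d_ml <- unitize(ml0)
  cur <- objective(d_ml)
  if (!is.finite(cur$value))
    stop("fewer than two valid contours per condyle")
  trace <- cur$value
  step <- config$usp_step_init
  iter <- 0
  total_tilt <- 0
  while (step >= config$usp_step_min && iter < config$usp_max_iter) {
    improved <- FALSE
    for (axis_vec in list(post, dist_dir)) {
      for (sgn in c(1, -1)) {
        iter <- iter + 1
        d_try <- as.numeric(rotation_about(axis_vec, sgn * step) %*% d_ml)
        if (line_angle(d_try, ml0) > config$usp_max_tilt) next
        cand <- objective(d_try)
        if (is.finite(cand$value) && cand$value < cur$value - config$usp_tol) {
          d_ml <- d_try; cur <- cand
          trace <- c(trace, cur$value)
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) step <- step / 2
  }
  pfea <- fit_line_tls(cur$foci)
  cea <- fit_line_tls(cur$centers)
  if (sum(pfea$direction * ml0) < 0) pfea$direction <- -pfea$direction
  if (sum(cea$direction * ml0) < 0) cea$direction <- -cea$direction
  if (sum(d_ml * ml0) < 0) d_ml <- -d_ml
  list(usp = plane3(colMeans(cur$foci), d_ml), pfea = pfea, cea = cea,
       dispersion = cur$value,
       diagnostics = list(trace = trace, iterations = iter,
                          n_foci = nrow(cur$foci),
                          converged = iter < config$usp_max_iter))
}

#' Detect the epicondyles by the three-candidate selection process
#'
#' Per side, three candidates exist: the intersection of the centre axis
#' (CEA) with the surface (EC_CEA), the extreme point along the unified
#' sagittal plane's mediolateral axis (EC_max) and the mapped template
#' epicondyle (EC_map).  EC_max is final unless EC_map is closer to EC_CEA
#' than EC_max is (the large-osteophyte guard); then the distal femur is
#' clipped with two balls centred at EC_CEA and EC_map, radius
#' |EC_CEA - EC_map|, and the extreme mediolateral point of the clipped
#' part is taken.
#'
#' @param distal_mesh Distal part `surface_mesh`.
#' @param d_ml USP mediolateral axis, lateral positive.
#' @param cea `line3` of the centre axis.
#' @param mapped_ec Named list with `MEC_map`, `LEC_map` points.
#' @return List with `mec`, `lec` and `diagnostics` (per-side branch and
#'   candidate points).
#' @export
detect_epicondyles <- function(distal_mesh, d_ml, cea, mapped_ec) {
  hits <- cpp_line_mesh(cea$point, cea$direction, distal_mesh$vertices,
                        distal_mesh$faces)
  if (length(hits$t) < 2) stop("centre axis misses the distal surface")
  v <- distal_mesh$vertices
  proj <- as.numeric(v %*% d_ml)
  one_side <- function(label) {
    medial <- label == "medial"
    tt <- if (medial) min(hits$t) else max(hits$t)
    ec_cea <- cea$point + tt * cea$direction
    ec_max <- v[if (medial) which.min(proj) else which.max(proj), ]
    ec_map <- mapped_ec[[if (medial) "MEC_map" else "LEC_map"]]
    d_map <- vnorm(ec_cea - ec_map)
    d_max <- vnorm(ec_cea - ec_max)
    if (d_map < d_max) {
      clipped <- tryCatch({
        a <- clip_mesh(distal_mesh, list(center = ec_cea, radius = d_map))
        b <- clip_mesh(distal_mesh, list(center = ec_map, radius = d_map))
        rbind(a$vertices, b$vertices)
      }, error = function(e) NULL)
      if (is.null(clipped)) stop("epicondyle fallback clip failed")
      pr <- as.numeric(clipped %*% d_ml)
      final <- clipped[if (medial) which.min(pr) else which.max(pr), ]
      branch <- "clipped"
    } else {
      final <- ec_max
      branch <- "ec_max"
    }
    list(point = final, branch = branch,
         candidates = list(ec_cea = ec_cea, ec_max = ec_max,
                           ec_map = ec_map))
  }
  med <- one_side("medial")
  lat <- one_side("lateral")
  list(mec = med$point, lec = lat$point,
       diagnostics = list(medial = med[c("branch", "candidates")],
                          lateral = lat[c("branch", "candidates")]))
}

# signed discrete curvature of a closed polyline in a plane (positive =
# convex for counter-clockwise orientation), 5-point smoothed
polyline_curvature <- function(u, w) {
  n <- length(u)
  im <- c(n, 1:(n - 1)); ip <- c(2:n, 1)
  ax <- u - u[im]; ay <- w - w[im]
  bx <- u[ip] - u; by <- w[ip] - w
  cross <- ax * by - ay * bx
  la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2)
  lc <- sqrt((u[ip] - u[im])^2 + (w[ip] - w[im])^2)
  curv <- 2 * cross / pmax(la * lb * lc, 1e-12)
  k <- stats::filter(c(curv[(n - 1):n], curv, curv[1:2]), rep(1 / 5, 5))
  as.numeric(k[3:(n + 2)])
}

#' Detect the intercondylar notch
#'
#' The PFEA's intersections with the condyles bound the intercondylar
#' sector.  Per sagittal cut of the sector, the boundary point between the
#' trochlear surface and the intercondylar fossa is the most anterior
#' strongly concave curvature extremum of the contour.  The temporary
#' notch combines the median posteroanterior coordinate of the boundary
#' points with the local maximum of the distal outline of the frontal
#' silhouette; the final notch is the boundary point nearest to it.
#'
#' @param mesh Full (closed) subject `surface_mesh`; the sagittal sector
#'   cuts are taken on it so that the contours are closed.
#' @param distal_mesh Distal part `surface_mesh` (frontal silhouette).
#' @param pfea `line3` posterior focal elliptic axis.
#' @param d_ml USP mediolateral axis.
#' @param post Posterior direction.
#' @param config See [femcoord_config()].
#' @return List with `icn`, `boundary_points` and `diagnostics`.
#' @export
detect_icn <- function(mesh, distal_mesh, pfea, d_ml, post,
                       config = femcoord_config()) {
  hits <- cpp_line_mesh(pfea$point, pfea$direction, distal_mesh$vertices,
                        distal_mesh$faces)
  ts <- sort(unique(round(hits$t, 6)))
  if (length(ts) < 4) stop("PFEA does not intersect both condyles")
  sector <- c(ts[2], ts[length(ts) - 1])  # inner condyle walls
  anterior <- -post
  dist_dir <- unitize(cross3(d_ml, post) *
                      sign(sum(cross3(d_ml, post) * c(-1, 0, 0))))
  # mediolateral bookkeeping axis orthogonal to the posterior and distal
  # directions: projecting onto the (tilted) cutting normal itself would
  # skew the mediolateral coordinate along the bone's length
  ml_axis <- unitize(cross3(post, dist_dir))
  if (sum(ml_axis * d_ml) < 0) ml_axis <- -ml_axis
  m_lo <- sum((pfea$point + sector[1] * pfea$direction) * ml_axis)
  m_hi <- sum((pfea$point + sector[2] * pfea$direction) * ml_axis)
  proj_ml <- as.numeric(distal_mesh$vertices %*% ml_axis)
  keep <- proj_ml > min(m_lo, m_hi) & proj_ml < max(m_lo, m_hi)
  # cut offsets across the sector, inset from the walls
  span <- sector[2] - sector[1]
  offs <- seq(sector[1] + 0.12 * span, sector[2] - 0.12 * span,
              length.out = config$icn_planes)
  boundary <- NULL
  for (t in offs) {
    p0 <- pfea$point + t * pfea$direction
    ct <- cut_mesh_with_plane(mesh, plane3(p0, d_ml))
    comps <- Filter(function(cmp) cmp$closed && nrow(cmp$points) >= 12,
                    ct$components)
    if (length(comps) == 0) next
    areas <- vapply(comps, `[[`, 0, "area")
    pts <- comps[[which.max(areas)]]$points
    pts <- resample_closed(pts, step = 0.9)
    c0 <- colMeans(pts)
    rel <- sweep(pts, 2, c0)
    u <- as.numeric(rel %*% anterior)
    w <- as.numeric(rel %*% dist_dir)
    # enforce counter-clockwise orientation in (u, w)
    n <- length(u)
    if (sum(u * w[c(2:n, 1)] - u[c(2:n, 1)] * w) < 0) {
      ord <- n:1
      pts <- pts[ord, , drop = FALSE]; u <- u[ord]; w <- w[ord]
    }
    curv <- polyline_curvature(u, w)
    # the fossa rims are step-like edges where the carved wall meets the
    # articular surface: locally the solid is an intersection of two
    # half-spaces, i.e. a sharp CONVEX crease, with smoothed curvature
    # well above every smooth surface patch of the bone (condyles,
    # trochlea, blend fillets are all below ~0.13 1/mm)
    crease <- which(curv > config$icn_curv_thresh)
    if (length(crease) == 0) next
    # restrict to the condyle neighbourhood (distance to the PFEA) and
    # take the most proximal crease: the fossa-roof rim separating the
    # trochlear surface from the intercondylar fossa
    rel_f <- sweep(pts[crease, , drop = FALSE], 2, pfea$point)
    perp <- rel_f - (rel_f %*% pfea$direction) %*% t(pfea$direction)
    near <- sqrt(rowSums(perp^2)) < config$icn_window
    crease <- crease[near]
    if (length(crease) == 0) next
    # the tessellation rounds each crease into a short arc of
    # above-threshold points; group contiguous runs, take the most
    # proximal run and use its curvature peak as the corner location
    runs <- split(crease, cumsum(c(1, diff(crease) > 2)))
    run_w <- vapply(runs, function(r) min(w[r]), 0)
    run <- runs[[which.min(run_w)]]
    # curvature-weighted mean of the run: a sub-sample estimate of the
    # corner, unbiased w.r.t. which side of the crease the peak lands on
    wt <- curv[run] - config$icn_curv_thresh
    corner <- colSums(pts[run, , drop = FALSE] * wt) / sum(wt)
    boundary <- rbind(boundary, corner)
  }
  if (is.null(boundary) || nrow(boundary) < 3)
    stop("no curvature extrema found in the intercondylar sector")
  # snap the sub-sample corner estimates back onto the surface
  boundary <- cpp_closest_on_mesh(boundary, mesh$vertices, mesh$faces)$point
  pa_med <- stats::median(boundary %*% post)
  sector_mesh <- submesh_by_vertices(distal_mesh, keep)
  env <- silhouette_envelope(sector_mesh, u_axis = dist_dir,
                             v_axis = ml_axis,
                             nbins = config$silhouette_bins)
  # distal outline = the envelope on the distal side; its local maximum
  # (the arch of the notch, i.e. the most proximal point of that outline)
  # gives the distoproximal and mediolateral components
  i_max <- which.min(env$hi)
  dp_val <- env$hi[i_max]
  ml_val <- env$v[i_max]
  # temporary notch point assembled in the orthonormal (ml, pa, dp) frame
  B <- cbind(ml_axis, post, dist_dir)
  tmp <- as.numeric(B %*% c(ml_val, pa_med, dp_val))
  nn <- cpp_nn(matrix(tmp, 1, 3), boundary)
  icn <- boundary[nn$index, ]
  list(icn = icn, boundary_points = boundary,
       diagnostics = list(temporary = tmp, n_boundary = nrow(boundary),
                          sector = sector))
}

#' Pass through mapped-only landmarks
#'
#' @param mapped Mapped anatomy from [map_anatomy()].
#' @return List with `sgt`, `lt` and a `mapped_only` flag vector.
#' @export
passthrough_landmarks <- function(mapped) {
  for (nm in c("SGT", "LT"))
    if (is.null(mapped$landmarks[[nm]])) stop("missing mapped landmark ", nm)
  list(sgt = mapped$landmarks$SGT, lt = mapped$landmarks$LT,
       mapped_only = c("SGT", "LT"))
}

# --------------------------------------------------------------------------
# Orchestration
# --------------------------------------------------------------------------

#' Run the full landmark detection pipeline
#'
#' Stage 1 (atlas registration) followed by stage 2 (a-priori refinement).
#' All outputs are expressed in the coordinates of the input mesh.
#'
#' @param mesh Subject `surface_mesh` (closed, complete femur, mm).
#' @param side `"left"` or `"right"`.
#' @param template An `atlas_template`.
#' @param config See [femcoord_config()].
#' @return Object of class `anatomy_result`: `landmarks` (named 3-vector
#'   rows: FHC, MEC, LEC, MPC, LPC, PTC, ICN, SGT, LT), `axes` (`line3`:
#'   shaft, neck, PFEA, CEA), `planes` (`plane3`: TTP, USP), `diagnostics`.
#' @export
detect_anatomy <- function(mesh, side = c("right", "left"),
                           template = default_template(),
                           config = femcoord_config()) {
  side <- match.arg(side)
  reg <- register_template(mesh, side, template, config)
  subject <- reg$subject
  mapped <- reg$mapped
  diag <- list(registration = reg$diagnostics)

  fh <- refine_fhc(mapped$regions$head)
  diag$fhc <- fh$diagnostics
  sh <- detect_shaft_axis(subject, fh$fhc)
  diag$shaft <- sh$diagnostics
  nk <- refine_neck_axis(subject, mapped$regions$neck, fh$fhc, config)
  diag$neck <- nk$diagnostics
  tp <- detect_ttp(subject, side, nk$axis, mapped$regions, config)
  diag$ttp <- tp$diagnostics

  v <- subject$vertices
  xr <- range(v[, 1])
  distal <- submesh_by_vertices(subject, v[, 1] < xr[1] + 0.45 * diff(xr))
  condyle_meshes <- list(
    medial = submesh_by_vertices(subject,
                                 mapped$region_indices$medial_condyle),
    lateral = submesh_by_vertices(subject,
                                  mapped$region_indices$lateral_condyle))
  ml0 <- unitize(tp$lpc - tp$mpc)  # medial -> lateral by part labels
  us <- compute_usp(condyle_meshes, mapped$regions, ml0, tp$ttp$normal,
                    config)
  diag$usp <- us$diagnostics
  ec <- detect_epicondyles(distal, us$usp$normal, us$cea,
                           mapped$landmarks[c("MEC_map", "LEC_map")])
  diag$epicondyles <- ec$diagnostics
  ic <- detect_icn(subject, distal, us$pfea, us$usp$normal, tp$ttp$normal,
                   config)
  diag$icn <- ic$diagnostics
  pt <- passthrough_landmarks(mapped)
  diag$mapped_only <- pt$mapped_only

  landmarks <- rbind(FHC = fh$fhc, MEC = ec$mec, LEC = ec$lec,
                     MPC = tp$mpc, LPC = tp$lpc, PTC = tp$ptc,
                     ICN = ic$icn, SGT = pt$sgt, LT = pt$lt)
  axes <- list(shaft = sh$axis, neck = nk$axis, PFEA = us$pfea,
               CEA = us$cea)
  planes <- list(TTP = tp$ttp, USP = us$usp)

  # transport back to input coordinates
  landmarks <- reg$to_input(landmarks)
  Rt <- t(reg$transforms$prereg %*% reg$transforms$tfcs$rotation)
  axes <- lapply(axes, function(a)
    line3(reg$to_input(a$point), as.numeric(Rt %*% a$direction)))
  planes <- lapply(planes, function(p)
    plane3(reg$to_input(p$point), as.numeric(Rt %*% p$normal)))
  diag$head_radius <- fh$radius * 1 / reg$transforms$scale
  structure(list(landmarks = landmarks, axes = axes, planes = planes,
                 side = side, diagnostics = diag),
            class = "anatomy_result")
}

#' @export
print.anatomy_result <- function(x, ...) {
  cat("<anatomy_result>", x$side, "femur\n")
  print(round(x$landmarks, 2))
  for (nm in names(x$axes))
    cat(sprintf("axis %-6s dir (%s)\n", nm,
                paste(round(x$axes[[nm]]$direction, 4), collapse = ", ")))
  invisible(x)
}

#' Serialize an anatomy result to JSON
#'
#' @param result An `anatomy_result` (optionally with `frames` attached).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_anatomy_json <- function(result, path) {
  out <- list(
    schema = "femcoord-anatomy-v1",
    side = result$side,
    landmarks = stats::setNames(
      lapply(seq_len(nrow(result$landmarks)),
             function(i) as.numeric(result$landmarks[i, ])),
      rownames(result$landmarks)),
    axes = lapply(result$axes, function(a)
      list(point = a$point, direction = a$direction)),
    planes = lapply(result$planes, function(p)
      list(point = p$point, normal = p$normal)))
  if (!is.null(result$frames))
    out$frames <- lapply(result$frames, function(f)
      list(origin = f$origin, axes = unname(apply(f$axes, 1, as.numeric,
                                                  simplify = FALSE))))
  out$diagnostics <- list(
    icp_residuals = result$diagnostics$registration$icp_residuals,
    neck_trace = result$diagnostics$neck$trace,
    usp_trace = result$diagnostics$usp$trace,
    ttp_iterations = result$diagnostics$ttp$iterations,
    mapped_only = result$diagnostics$mapped_only)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
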