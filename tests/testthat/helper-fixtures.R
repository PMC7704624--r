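# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; no binary fixtures on disk.

fx_cache <- new.env(parent = emptyenv())

fx_get <- function(key, maker) {
  if (is.null(fx_cache[[key]])) fx_cache[[key]] <- maker()
  fx_cache[[key]]
}

fx_template <- function() default_template()

fx_default <- function() fx_get("default_femur", function()
  generate_femur(femur_spec()))

fx_reg <- function() fx_get("default_reg", function()
  register_template(fx_default()$mesh, "right", fx_template()))

# full stage-2 chain on the default femur, in registration space
fx_stages <- function() fx_get("default_stages", function() {
  reg <- fx_reg()
  subject <- reg$subject
  mapped <- reg$mapped
  fh <- refine_fhc(mapped$regions$head)
  sh <- detect_shaft_axis(subject, fh$fhc)
  nk <- refine_neck_axis(subject, mapped$regions$neck, fh$fhc)
  tp <- detect_ttp(subject, "right", nk$axis, mapped$regions)
  v <- subject$vertices
  xr <- range(v[, 1])
  distal <- femcoord:::submesh_by_vertices(subject,
                                           v[, 1] < xr[1] + 0.45 * diff(xr))
  cm <- list(
    medial = femcoord:::submesh_by_vertices(
      subject, mapped$region_indices$medial_condyle),
    lateral = femcoord:::submesh_by_vertices(
      subject, mapped$region_indices$lateral_condyle))
  ml0 <- femcoord:::unitize(tp$lpc - tp$mpc)
  us <- compute_usp(cm, mapped$regions, ml0, tp$ttp$normal)
  ec <- detect_epicondyles(distal, us$usp$normal, us$cea,
                           mapped$landmarks[c("MEC_map", "LEC_map")])
  ic <- detect_icn(subject, distal, us$pfea, us$usp$normal, tp$ttp$normal)
  list(reg = reg, fh = fh, sh = sh, nk = nk, tp = tp, us = us, ec = ec,
       ic = ic, distal = distal)
})

fx_default_result <- function() fx_get("default_result", function()
  detect_anatomy(fx_default()$mesh, "right", fx_template()))

# coarse femur for fast CLI / harness tests
fx_coarse_spec <- function() femur_spec(tessellation = 3.2)
fx_coarse <- function() fx_get("coarse_femur", function()
  generate_femur(fx_coarse_spec()))

# --- small analytic solids --------------------------------------------------

make_cube <- function(center = c(0, 0, 0), half = c(0.5, 0.5, 0.5)) {
  v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  v <- sweep(v %*% diag(half), 2, center, "+")
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

make_implicit <- function(f, lower, upper, h) {
  femcoord:::extract_isosurface(f, lower, upper, h)
}

make_sphere_mesh <- function(r = 10, h = 0.5, center = c(0, 0, 0)) {
  make_implicit(function(p) sqrt(rowSums(sweep(p, 2, center)^2)) - r,
                center - r - 3 * h, center + r + 3 * h, h)
}

# random rigid transforms for equivariance property tests
random_transforms <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    rigid_transform(femcoord:::euler_xyz_to_matrix(stats::runif(1, -180, 180),
                                                   stats::runif(1, -90, 90),
                                                   stats::runif(1, -180, 180)),
                    stats::runif(3, -100, 100)))
}

line_angle_deg <- function(a, b) {
  x <- angle_between(a, b)
  min(x, 180 - x)
}
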