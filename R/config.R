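# One namespace for every tunable of the pipeline, with the package
# defaults.  Values the underlying publications leave open are decided
# here and documented in the methods vignette.

#' Pipeline configuration
#'
#' All tolerances and step sizes of the detection pipeline in one place.
#' Any subset can be overridden via `...`.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of class `femcoord_config`.
#'
#' @section Defaults:
#' \describe{
#'   \item{icp_stiffness, icp_steps, icp_factor, icp_inner}{Nonrigid ICP:
#'     initial stiffness 100, 8 geometric levels with factor 0.7, 2
#'     closest-point/solve alternations per level.}
#'   \item{neck_step_init, neck_step_min, neck_tol, neck_max_iter}{Neck
#'     axis coordinate descent: tilt step 1 -> 0.1 degrees, perimeter
#'     improvement tolerance 1e-4 mm, at most 200 iterations.}
#'   \item{ttp_tol, ttp_max_iter}{Table-top fixed point: update rotation
#'     below 1e-6 rad, at most 50 iterations.}
#'   \item{usp_planes, usp_arc_margin, usp_step_init, usp_step_min,
#'     usp_tol, usp_max_iter, usp_max_tilt}{Sagittal stack: 15 planes per
#'     condyle, articulating arc = posterior-distal quadrant +/- 20
#'     degrees, tilt step 1 -> 0.1 degrees, dispersion tolerance 1e-5
#'     mm^2, tilt limited to 10 degrees about the initial condylar axis.}
#'   \item{icn_planes, icn_curv_thresh, icn_window, silhouette_bins}{Notch
#'     detection: 15 sector cuts, convex crease threshold 0.2 1/mm
#'     (separates the sharp fossa-rim edges from smooth articular
#'     patches), rim candidates within 28 mm of the PFEA, 128 silhouette
#'     scanlines.}
#'   \item{seed}{Seed for the robustness harness (the detection itself is
#'     deterministic).}
#' }
#' @export
femcoord_config <- function(...) {
  cfg <- list(
    icp_stiffness = 100, icp_steps = 8, icp_factor = 0.7, icp_inner = 2,
    neck_step_init = 1, neck_step_min = 0.1, neck_tol = 1e-4,
    neck_max_iter = 200,
    ttp_tol = 1e-6, ttp_max_iter = 50,
    usp_planes = 15, usp_arc_margin = 20, usp_step_init = 1,
    usp_step_min = 0.1, usp_tol = 1e-5, usp_max_iter = 120,
    usp_max_tilt = 10,
    icn_planes = 15, icn_curv_thresh = 0.2, icn_window = 28,
    silhouette_bins = 128,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  positive <- setdiff(names(cfg), c("icn_curv_thresh", "seed"))
  if (any(unlist(cfg[positive]) <= 0))
    stop("configuration tolerances and step sizes must be positive")
  structure(cfg, class = "femcoord_config")
}

# read key = value overrides from a plain-text config file
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- utils::type.convert(x[2], as.is = TRUE)
    v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(femcoord_config, vals)
}
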