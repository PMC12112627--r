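#' Analysis configuration
#'
#' All tunable parameters of the pipeline, with defaults matching the
#' standard acquisition and measurement settings: lumen HU window 100-600
#' (inclusive), calcification strictly above 600 HU, 0.2 mm slice spacing,
#' 360 radial rays (1 degree), lumen smoothing factor 0.3.
#'
#' @param hu_lumen_lo,hu_lumen_hi inclusive lumen HU window.
#' @param hu_calc_min strict lower calcification threshold (HU).
#' @param proximity_mm calcification-to-lumen proximity rule (mm).
#' @param smooth_factor,smooth_iters Laplacian lumen-mesh smoothing.
#' @param step_mm cross-section spacing along the centerline (mm).
#' @param n_rays radial rays per slice.
#' @param curvature_sigma_mm curvature smoothing bandwidth (mm).
#' @param boundary_fractions,boundary_overrides_mm Bouthillier boundary
#'   fallback fractions / explicit arclengths.
#' @param contact_mm surface-contact distance (NULL = voxel diagonal).
#' @param seed integer seed for any randomized step.
#' @return list of class `run_config`.
#' @export
run_config <- function(hu_lumen_lo = 100, hu_lumen_hi = 600,
                       hu_calc_min = 600, proximity_mm = 3,
                       smooth_factor = 0.3, smooth_iters = 20L,
                       step_mm = 0.2, n_rays = 360L,
                       curvature_sigma_mm = 2,
                       boundary_fractions = c(0.25, 0.40, 0.60, 0.80),
                       boundary_overrides_mm = NULL,
                       contact_mm = NULL, seed = 1L) {
  cfg <- list(hu_lumen_lo = hu_lumen_lo, hu_lumen_hi = hu_lumen_hi,
              hu_calc_min = hu_calc_min, proximity_mm = proximity_mm,
              smooth_factor = smooth_factor,
              smooth_iters = as.integer(smooth_iters),
              step_mm = step_mm, n_rays = as.integer(n_rays),
              curvature_sigma_mm = curvature_sigma_mm,
              boundary_fractions = boundary_fractions,
              boundary_overrides_mm = boundary_overrides_mm,
              contact_mm = contact_mm, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Analyze one artery end to end
#'
#' Runs the full pipeline: HU masking (when a volume is given), lumen
#' meshing with asymmetric smoothing (the lumen mesh is smoothed,
#' calcification stays voxels), centerline extraction, Bouthillier
#' labelling, perpendicular cross-sections with radial ray measurements,
#' 3D calcification bodies, stenosis, and the per-artery record.
#'
#' @param volume an [hu_volume()], or NULL when masks are supplied.
#' @param lumen a lumen [binary_mask()] or [tri_mesh()]; derived from
#'   `volume` by HU thresholding when NULL.
#' @param calc a calcification [binary_mask()]; derived from `volume` when
#'   NULL and a volume is given.
#' @param side `"left"` or `"right"` ICA.
#' @param endpoints 2 x 3 matrix of world mm endpoints (proximal first).
#' @param config a [run_config()].
#' @param seeds optional lumen seed points for seeded thresholding.
#' @return list of class `artery_analysis`: `record` (one-row tibble),
#'   `slices`, `slice_bodies`, `bodies`, `stenosis`, `labels`,
#'   `centerline`, `lumen_mesh`, `log`.
#' @export
analyze_artery <- function(volume = NULL, lumen = NULL, calc = NULL,
                           side = c("left", "right"), endpoints,
                           config = run_config(), seeds = NULL) {
  side <- match.arg(side)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(nm, expr) {
    t1 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[stage %s] %s", nm, conditionMessage(e)), call. = FALSE))
    timings[[nm]] <<- proc.time()[["elapsed"]] - t1
    val
  }
  timings <- list()
  if (is.null(lumen)) {
    if (is.null(volume)) stop("either a volume or a lumen mask is required")
    lumen <- stage("mask_lumen", threshold_lumen(
      volume, config$hu_lumen_lo, config$hu_lumen_hi, seeds = seeds))
  }
  lumen_mask <- NULL
  lumen_mesh <- NULL
  if (inherits(lumen, "binary_mask")) {
    lumen_mask <- lumen
    lumen_mesh <- stage("mesh_lumen", smooth_lumen_mesh(
      mask_to_mesh(lumen_mask), config$smooth_factor, config$smooth_iters))
  } else if (inherits(lumen, "tri_mesh")) {
    lumen_mesh <- lumen
    lumen_mask <- stage("rasterize_lumen", mesh_to_mask(lumen))
  } else stop("lumen must be a binary_mask or tri_mesh")
  if (is.null(calc) && !is.null(volume)) {
    calc <- stage("mask_calcification", extract_calcification(
      volume, lumen_mask, config$hu_calc_min, config$proximity_mm))
  }
  if (!is.null(calc) && !any(calc$values)) calc <- NULL
  cl <- stage("centerline", extract_centerline(
    lumen_mask, endpoints, step = config$step_mm,
    curvature_sigma_mm = config$curvature_sigma_mm))
  labels <- stage("bouthillier", label_bouthillier(
    cl, sigma_mm = config$curvature_sigma_mm,
    boundary_fractions = config$boundary_fractions,
    boundary_overrides_mm = config$boundary_overrides_mm))
  xs <- stage("slices", generate_slices(lumen_mesh, calc, cl,
                                        n_rays = config$n_rays))
  cb <- NULL
  sten <- NULL
  if (!is.null(calc)) {
    cb <- stage("bodies", connect_bodies(xs, calc))
    if (nrow(cb$slice_bodies))
      sten <- stage("stenosis", stenosis(xs, cb))
    else cb <- NULL
  }
  record <- stage("aggregate", aggregate_artery(
    xs, cl, labels, cb, lumen_mesh, calc, side, config$contact_mm))
  structure(list(
    record = record, slices = xs$table,
    slice_bodies = if (is.null(cb)) NULL else cb$slice_bodies,
    bodies = if (is.null(cb)) NULL else cb$bodies,
    stenosis = sten, labels = labels, centerline = cl,
    lumen_mesh = lumen_mesh, cross_sections = xs,
    log = list(config = config, timings = timings,
               total_s = proc.time()[["elapsed"]] - t0)),
    class = "artery_analysis")
}

#' @export
print.artery_analysis <- function(x, ...) {
  cat("<artery_analysis>\n")
  print(tidyr::pivot_longer(x$record, -dplyr::any_of("side"),
                            names_to = "metric", values_to = "value",
                            values_transform = as.character), n = Inf)
  invisible(x)
}

#' Write analysis outputs to a directory
#'
#' Per-artery record as JSON and one-row CSV, per-slice and per-body
#' tables as CSV, centerline as CSV (`x, y, z, s, label`).
#'
#' @param analysis an `artery_analysis`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_artery_outputs <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(record_json = file.path(dir, "artery_record.json"),
             record_csv = file.path(dir, "artery_record.csv"),
             slices = file.path(dir, "slices.csv"),
             slice_bodies = file.path(dir, "slice_bodies.csv"),
             centerline = file.path(dir, "centerline.csv"))
  jsonlite::write_json(as.list(analysis$record), paths["record_json"],
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  utils::write.csv(analysis$record, paths["record_csv"], row.names = FALSE)
  utils::write.csv(analysis$slices, paths["slices"], row.names = FALSE)
  if (!is.null(analysis$slice_bodies))
    utils::write.csv(
      dplyr::select(analysis$slice_bodies, -dplyr::any_of("theta_deg")),
      paths["slice_bodies"], row.names = FALSE)
  cl <- analysis$centerline
  utils::write.csv(
    data.frame(x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
               s = cl$arclength, label = as.character(analysis$labels$label)),
    paths["centerline"], row.names = FALSE)
  invisible(paths)
}
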