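# Shared phantom fixtures, built once per test session. All fixtures are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Straight cylinder, r = 2 mm, 80 mm, one 60-degree wedge of realistic
# thickness; analyzed end to end through the mask route.
fix_cylinder <- function() fixture("cylinder", function() {
  w <- wedge_spec(30, 40, theta_center_deg = 90, arc_width_deg = 60,
                  thickness_mm = 1.2, gap_mm = 0.2)
  spec <- phantom_spec(curve_line(80), 2, list(w), side = "left")
  vox <- voxelize_phantom(spec)
  meshes <- build_phantom_meshes(spec)
  ep <- curve_eval(spec$curve, c(0.2, 79.8))$points
  analysis <- analyze_artery(volume = vox$volume, side = "left",
                             endpoints = ep)
  list(spec = spec, truth = phantom_truth(spec), vox = vox,
       meshes = meshes, endpoints = ep, analysis = analysis)
})

# Carotid-siphon composite with two planted wedges; the main
# parameter-recovery fixture.
fix_siphon <- function() fixture("siphon", function() {
  cv <- carotid_siphon_curve()
  w1 <- wedge_spec(36, 46, theta_center_deg = 180, arc_width_deg = 70,
                   thickness_mm = 1.5, gap_mm = 0.2)
  w2 <- wedge_spec(61, 65, theta_center_deg = 30, arc_width_deg = 40,
                   thickness_mm = 1.2, gap_mm = 0.3)
  spec <- phantom_spec(cv, 2, list(w1, w2), side = "left")
  vox <- voxelize_phantom(spec)
  ep <- curve_eval(cv, c(0.2, cv$length_mm - 0.2))$points
  analysis <- analyze_artery(volume = vox$volume, side = "left",
                             endpoints = ep)
  list(spec = spec, truth = phantom_truth(spec), vox = vox,
       endpoints = ep, analysis = analysis,
       boundaries_mm = attr(cv, "boundaries_mm"))
})

# Straight tube with a linear taper narrowing co-located with one wedge:
# the analytic stenosis fixture (maximal local stenosis ~61%, well inside
# the 50-70 severity band).
fix_taper <- function() fixture("taper", function() {
  prof <- radius_profile(data.frame(
    s_start = c(0, 30, 50), s_end = c(30, 50, 80),
    shape = c("constant", "linear_taper", "constant"),
    r_start = c(2, 2, 1.25), r_end = c(2, 1.25, 1.25)))
  w <- wedge_spec(32, 48, theta_center_deg = 200, arc_width_deg = 50,
                  thickness_mm = 1.2, gap_mm = 0.2)
  spec <- phantom_spec(curve_line(80), prof, list(w), side = "right")
  vox <- voxelize_phantom(spec)
  ep <- curve_eval(spec$curve, c(0.2, 79.8))$points
  analysis <- analyze_artery(volume = vox$volume, side = "right",
                             endpoints = ep)
  list(spec = spec, profile = prof, truth = phantom_truth(spec), vox = vox,
       endpoints = ep, analysis = analysis)
})

# A synthetic, non-voxel cross-section with crisp radial intervals: a
# circular lumen of radius r and calcified rays at the given integer
# degrees, each with intervals (r_in, r_out).
synthetic_section <- function(member_deg, r_in, r_out, lumen_r = 2,
                              n_rays = 360L, s_mm = 0, index = 1L) {
  iv <- vector("list", n_rays)
  for (d in member_deg) iv[[d + 1L]] <- cbind(r_in, r_out)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  contour <- cbind(lumen_r * cos(th), lumen_r * sin(th))
  list(index = index, s_mm = s_mm, valid = TRUE,
       origin = c(0, 0, s_mm), normal = c(0, 0, 1),
       u = c(1, 0, 0), v = c(0, 1, 0),
       contour = contour, centroid = c(0, 0),
       area_mm2 = pi * lumen_r^2,
       lumen_radius = rep(lumen_r, n_rays),
       theta_deg = 0:(n_rays - 1L),
       calc_intervals = iv, ray_extent = NULL, ray_polar = NULL)
}

# A synthetic cross_sections object holding a lumen-area profile, for
# stenosis unit tests (no geometry needed).
synthetic_sections_table <- function(areas, valid = rep(TRUE, length(areas)),
                                     step = 0.2) {
  tab <- tibble::tibble(
    index = seq_along(areas),
    s_mm = (seq_along(areas) - 1) * step,
    valid = valid,
    lumen_area_mm2 = ifelse(valid, areas, NA_real_))
  tab$diameter_mm <- 2 * sqrt(tab$lumen_area_mm2 / pi)
  structure(list(sections = list(), table = tab, n_rays = 360L),
            class = "cross_sections")
}

# A minimal calc_bodies object from (slice index, body id, area) triples.
synthetic_bodies <- function(index, body, area = 1, s_mm = NULL,
                             step = 0.2) {
  if (is.null(s_mm)) s_mm <- (index - 1) * step
  st <- tibble::tibble(index = index, s_mm = s_mm,
                       body_local_id = 1L, area_mm2 = area,
                       arc_width_deg = 10, thickness_mm = 1, gap_mm = 0.1,
                       theta_deg = replicate(length(index), 0,
                                             simplify = FALSE),
                       body = body)
  bodies <- if (length(index)) {
    dplyr::summarise(
      dplyr::group_by(st, body),
      n_slices = dplyr::n_distinct(index),
      s_min = min(s_mm), s_max = max(s_mm),
      burden_mm2 = sum(area_mm2), .groups = "drop")
  } else {
    tibble::tibble(body = integer(), n_slices = integer(),
                   s_min = numeric(), s_max = numeric(),
                   burden_mm2 = numeric())
  }
  structure(list(slice_bodies = st, bodies = bodies, label_volume = NULL),
            class = "calc_bodies")
}
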