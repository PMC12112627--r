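#' Lumen radius profile along a phantom centerline
#'
#' Piecewise radius profile tiling `[0, length]`. Shapes: `constant`,
#' `linear_taper` (linear from `r_start` to `r_end`), `smooth_bump`
#' (raised-cosine excursion from `r_start` to `r_end` at mid-segment and
#' back; `r_end < r_start` gives a smooth focal narrowing — the analytic
#' stenosis case).
#'
#' @param segments data frame or tibble with columns `s_start`, `s_end`,
#'   `shape`, `r_start`, `r_end` (mm / shape name / mm / mm).
#' @return An object of class `radius_profile`.
#' @export
radius_profile <- function(segments) {
  segments <- tibble::as_tibble(segments)
  req <- c("s_start", "s_end", "shape", "r_start", "r_end")
  stopifnot(all(req %in% names(segments)))
  segments <- dplyr::arrange(segments, .data$s_start)
  if (any(segments$r_start <= 0) || any(segments$r_end <= 0))
    stop("all radii must be positive")
  if (nrow(segments) > 1) {
    gaps <- segments$s_start[-1] - segments$s_end[-nrow(segments)]
    if (any(abs(gaps) > 1e-9)) stop("radius segments must tile without gaps or overlap")
  }
  structure(list(segments = segments), class = "radius_profile")
}

#' @rdname radius_profile
#' @param r_mm constant radius.
#' @param length_mm profile length.
#' @export
radius_constant <- function(r_mm, length_mm) {
  radius_profile(tibble::tibble(s_start = 0, s_end = length_mm,
                                shape = "constant", r_start = r_mm,
                                r_end = r_mm))
}

#' Evaluate a radius profile
#' @param profile a [radius_profile].
#' @param s arclengths (mm), clamped to the profile support.
#' @return radii in mm.
#' @export
radius_at <- function(profile, s) {
  sg <- profile$segments
  s <- pmin(pmax(s, min(sg$s_start)), max(sg$s_end))
  k <- pmin(findInterval(s, c(sg$s_start, max(sg$s_end)),
                         rightmost.closed = TRUE), nrow(sg))
  frac <- (s - sg$s_start[k]) / pmax(sg$s_end[k] - sg$s_start[k], 1e-12)
  out <- numeric(length(s))
  cs <- sg$shape[k] == "constant"
  out[cs] <- sg$r_start[k][cs]
  lt <- sg$shape[k] == "linear_taper"
  out[lt] <- sg$r_start[k][lt] + frac[lt] * (sg$r_end[k][lt] - sg$r_start[k][lt])
  sb <- sg$shape[k] == "smooth_bump"
  out[sb] <- sg$r_start[k][sb] +
    (sg$r_end[k][sb] - sg$r_start[k][sb]) * sin(pi * frac[sb])^2
  out
}

#' Calcified wedge specification
#'
#' A wedge is an annular sector swept along the centerline in the transported
#' frame: between arclengths `s_start` and `s_end`, covering `arc_width_deg`
#' of angle centred at `theta_center_deg`, radially from the lumen surface
#' plus `gap_mm` outward over `thickness_mm`.
#'
#' @param s_start,s_end longitudinal extent along the centerline (mm).
#' @param theta_center_deg angular centre in the transported frame, `[0,360)`.
#' @param arc_width_deg angular width in `(0, 360]`.
#' @param thickness_mm radial thickness (> 0).
#' @param gap_mm radial clearance between lumen boundary and the inner wedge
#'   boundary (>= 0).
#' @return An object of class `wedge_spec`.
#' @export
wedge_spec <- function(s_start, s_end, theta_center_deg, arc_width_deg,
                       thickness_mm, gap_mm = 0) {
  stopifnot(s_start < s_end, arc_width_deg > 0, arc_width_deg <= 360,
            thickness_mm > 0, gap_mm >= 0)
  structure(list(s_start = s_start, s_end = s_end,
                 theta_center_deg = theta_center_deg %% 360,
                 arc_width_deg = arc_width_deg,
                 thickness_mm = thickness_mm, gap_mm = gap_mm),
            class = "wedge_spec")
}

#' Vessel phantom specification
#'
#' Bundles a centerline curve, a lumen radius profile, calcified wedges and
#' the imaging parameters of a synthetic CTA volume. The three HU levels are
#' placed so that the standard thresholds (lumen 100-600 HU inclusive,
#' calcification strictly above 600 HU) separate the classes exactly:
#' defaults 0 / 300 / 800 HU.
#'
#' @param curve a [curve_spec].
#' @param radius a [radius_profile] (or a single number for a constant
#'   radius over the curve length).
#' @param wedges list of [wedge_spec] (may be empty).
#' @param voxel_mm isotropic voxel size (mm).
#' @param hu_background,hu_lumen,hu_calc HU levels (background < 100,
#'   lumen within `[100, 600]`, calcification > 600).
#' @param side `"left"` or `"right"` ICA; fixes the medial/lateral axes.
#' @param seed integer seed recorded with the spec (phantom synthesis is
#'   deterministic; the seed keys any downstream randomised use).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(curve, radius, wedges = list(), voxel_mm = 0.3,
                         hu_background = 0, hu_lumen = 300, hu_calc = 800,
                         side = c("left", "right"), seed = 1L) {
  side <- match.arg(side)
  if (is.numeric(radius)) radius <- radius_constant(radius, curve$length_mm)
  stopifnot(inherits(curve, "curve_spec"), inherits(radius, "radius_profile"))
  if (hu_lumen < 100 || hu_lumen > 600)
    stop("hu_lumen must lie in [100, 600]")
  if (hu_calc <= 600) stop("hu_calc must exceed 600")
  if (hu_background >= 100) stop("hu_background must be below 100")
  if (length(wedges) && inherits(wedges, "wedge_spec")) wedges <- list(wedges)
  for (w in wedges) {
    stopifnot(inherits(w, "wedge_spec"))
    if (w$s_end > curve$length_mm + 1e-9)
      stop("wedge extends beyond the curve length")
  }
  structure(list(curve = curve, radius = radius, wedges = wedges,
                 voxel_mm = voxel_mm, hu_background = hu_background,
                 hu_lumen = hu_lumen, hu_calc = hu_calc, side = side,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

wedge_table <- function(spec) {
  if (!length(spec$wedges))
    return(matrix(numeric(0), 0, 6))
  do.call(rbind, lapply(spec$wedges, function(w)
    c(w$s_start, w$s_end, w$theta_center_deg, w$arc_width_deg,
      w$thickness_mm, w$gap_mm)))
}

#' Voxelize a phantom into an HU volume and masks
#'
#' Classifies every voxel centre against the analytic tube and wedge
#' geometry: calcification where the centre falls inside a wedge, lumen
#' where it falls inside the tube, background elsewhere. Output grid is
#' RAS-aligned with an isotropic `voxel_mm` spacing and a 3 mm margin
#' around the geometry.
#'
#' @param spec a [phantom_spec].
#' @param max_voxels refuse grids larger than this many voxels
#'   (default `512^3`); guards desk-scale runs.
#' @return list: `volume` ([hu_volume]), `lumen`, `calcification`
#'   ([binary_mask]), `wedge_id` (integer array: which wedge claimed each
#'   calcified voxel).
#' @export
voxelize_phantom <- function(spec, max_voxels = 512^3) {
  rmin <- min(spec$radius$segments$r_start, spec$radius$segments$r_end)
  if (spec$voxel_mm > rmin / 3)
    stop(sprintf("voxel size %.3g mm too coarse for minimum radius %.3g mm (need <= r/3)",
                 spec$voxel_mm, rmin))
  cs <- sample_curve(spec$curve, ds = min(0.05, spec$voxel_mm / 4))
  rr <- radius_at(spec$radius, cs$s)
  reach <- max(rr) + max(c(0, vapply(spec$wedges, function(w)
    w$gap_mm + w$thickness_mm, numeric(1))))
  margin <- 3
  lo <- apply(cs$points, 2, min) - reach - margin
  hi <- apply(cs$points, 2, max) + reach + margin
  dims <- as.integer(ceiling((hi - lo) / spec$voxel_mm)) + 1L
  if (prod(as.numeric(dims)) > max_voxels)
    stop(sprintf("phantom grid %s exceeds the voxel cap (%d voxels)",
                 paste(dims, collapse = "x"), as.integer(max_voxels)))
  cl <- .classify_phantom_voxels(
    dims, rep(spec$voxel_mm, 3), lo, cs$points, cs$s, rr,
    cs$tangents, cs$u, cs$v, wedge_table(spec),
    search_mm = reach + 2 * spec$voxel_mm)
  hu <- array(spec$hu_background, dims)
  hu[cl$class == 1L] <- spec$hu_lumen
  hu[cl$class == 2L] <- spec$hu_calc
  list(
    volume = hu_volume(hu, spec$voxel_mm, lo),
    lumen = binary_mask(array(cl$class == 1L, dims), spec$voxel_mm, lo,
                        role = "lumen"),
    calcification = binary_mask(array(cl$class == 2L, dims), spec$voxel_mm,
                                lo, role = "calcification"),
    wedge_id = cl$wedge)
}

#' Build analytic surface meshes for a phantom
#'
#' Lumen tube: rings of vertices swept along the centerline at the local
#' radius, closed with end-cap fans. Wedges: swept annular sectors with
#' inner/outer shells, side walls and end walls. Sampling density is chosen
#' so the tube lateral surface area is within 1 percent of the closed form.
#'
#' @param spec a [phantom_spec].
#' @param ds longitudinal sampling step (mm).
#' @param n_theta angular resolution of the tube rings.
#' @return list: `lumen` (a `tri_mesh`), `calcifications` (list of
#'   `tri_mesh`, one per wedge).
#' @export
build_phantom_meshes <- function(spec, ds = 0.2, n_theta = 96L) {
  for (w in spec$wedges)
    if (w$gap_mm < 0) stop("wedge intersects the lumen interior (gap < 0)")
  cs <- sample_curve(spec$curve, ds = ds)
  rr <- radius_at(spec$radius, cs$s)
  lumen <- tube_mesh(cs, rr, n_theta, role = "lumen")
  calcs <- lapply(seq_along(spec$wedges), function(i) {
    w <- spec$wedges[[i]]
    wedge_mesh(spec, w, ds = ds)
  })
  list(lumen = lumen, calcifications = calcs)
}

tube_mesh <- function(cs, rr, n_theta, role) {
  n <- nrow(cs$points)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  verts <- matrix(0, n * n_theta + 2L, 3)
  for (i in seq_len(n)) {
    ring <- cs$points[rep(i, n_theta), ] +
      rr[i] * (outer(cos(th), cs$u[i, ]) + outer(sin(th), cs$v[i, ]))
    verts[(i - 1L) * n_theta + seq_len(n_theta), ] <- ring
  }
  c0 <- n * n_theta + 1L   # start cap centre
  c1 <- n * n_theta + 2L   # end cap centre
  verts[c0, ] <- cs$points[1, ]
  verts[c1, ] <- cs$points[n, ]
  faces <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * n_theta + seq_len(n_theta)
    b <- a %% (n_theta) + (i - 1L) * n_theta + 1L  # next around ring
    a2 <- a + n_theta
    b2 <- b + n_theta
    faces[[i]] <- rbind(cbind(a, b, a2), cbind(b, b2, a2))
  }
  ring1 <- seq_len(n_theta)
  ringn <- (n - 1L) * n_theta + seq_len(n_theta)
  faces[[n]] <- rbind(
    cbind(ring1, c0, ring1 %% n_theta + 1L),
    cbind(ringn %% n_theta + (n - 1L) * n_theta + 1L, c1, ringn))
  tri_mesh(verts, do.call(rbind, faces), role = role)
}

wedge_mesh <- function(spec, w, ds = 0.2, dtheta_deg = 2) {
  sub <- seq(w$s_start, w$s_end, length.out = max(2L, ceiling((w$s_end - w$s_start) / ds) + 1L))
  ev <- curve_eval(spec$curve, sub)
  full <- sample_curve(spec$curve, ds = min(0.05, ds / 2))
  fr_u <- apply_interp_rows(full$s, full$u, sub)
  fr_v <- apply_interp_rows(full$s, full$v, sub)
  rr <- radius_at(spec$radius, sub)
  nth <- max(2L, ceiling(w$arc_width_deg / dtheta_deg) + 1L)
  th <- (w$theta_center_deg + seq(-w$arc_width_deg / 2, w$arc_width_deg / 2,
                                  length.out = nth)) * pi / 180
  ns <- length(sub)
  rin <- rr + w$gap_mm
  rout <- rin + w$thickness_mm
  vin <- matrix(0, ns * nth, 3)
  vout <- matrix(0, ns * nth, 3)
  for (i in seq_len(ns)) {
    dirm <- outer(cos(th), fr_u[i, ]) + outer(sin(th), fr_v[i, ])
    base <- ev$points[rep(i, nth), ]
    vin[(i - 1L) * nth + seq_len(nth), ] <- base + rin[i] * dirm
    vout[(i - 1L) * nth + seq_len(nth), ] <- base + rout[i] * dirm
  }
  verts <- rbind(vin, vout)
  off <- ns * nth
  quad <- function(a, b, d, cc) rbind(cbind(a, b, cc), cbind(a, cc, d))
  faces <- list()
  for (i in seq_len(ns - 1L)) {
    for (j in seq_len(nth - 1L)) {
      a <- (i - 1L) * nth + j
      b <- a + 1L
      a2 <- a + nth
      b2 <- b + nth
      faces[[length(faces) + 1L]] <- quad(a, a2, b, b2)              # inner shell
      faces[[length(faces) + 1L]] <- quad(a + off, b + off, a2 + off, b2 + off) # outer
    }
  }
  if (w$arc_width_deg < 360) {    # side walls at theta extremes
    for (i in seq_len(ns - 1L)) { # (a full ring closes on itself instead)
      a <- (i - 1L) * nth + 1L; a2 <- a + nth
      faces[[length(faces) + 1L]] <- quad(a, b = a + off, d = a2, cc = a2 + off)
      b <- i * nth; b2 <- b + nth
      faces[[length(faces) + 1L]] <- quad(b, b2, b + off, b2 + off)
    }
  }
  for (j in seq_len(nth - 1L)) {  # end walls at s extremes
    a <- j; b <- j + 1L
    faces[[length(faces) + 1L]] <- quad(a, b, a + off, b + off)
    a <- (ns - 1L) * nth + j; b <- a + 1L
    faces[[length(faces) + 1L]] <- quad(a, a + off, b, b + off)
  }
  tri_mesh(verts, do.call(rbind, faces), role = "calcification")
}

apply_interp_rows <- function(s, m, snew) {
  out <- vapply(1:3, function(j) stats::approx(s, m[, j], xout = snew,
                                               rule = 2)$y,
                numeric(length(snew)))
  out <- matrix(out, length(snew), 3)
  out / sqrt(rowSums(out^2))
}

orientation_classes <- function(side) {
  sgn <- if (side == "right") -1 else 1
  list(medial = c(sgn, 0, 0),
       lateral = c(-sgn, 0, 0),
       anteroinferior = c(0, 1, -1) / sqrt(2),
       posterosuperior = c(0, -1, 1) / sqrt(2))
}

classify_direction <- function(dirs, side) {
  refs <- orientation_classes(side)
  refm <- do.call(cbind, refs)
  dots <- dirs %*% refm
  names(refs)[max.col(dots, ties.method = "last")]
}

#' Closed-form ground truth for a phantom
#'
#' Every downstream metric derived analytically from the specification,
#' never from the voxelized output: tortuosity, per-wedge arc width /
#' thickness / extent / gap / orientation class, calcification count,
#' total longitudinal extent, the lumen area function, cumulative and
#' maximal local stenosis with the severity category.
#'
#' @param spec a [phantom_spec].
#' @return A list of class `phantom_truth`.
#' @export
phantom_truth <- function(spec) {
  L <- spec$curve$length_mm
  ends <- curve_eval(spec$curve, c(0, L))$points
  chord <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  ti <- if (chord < 1e-12) Inf else L / chord - 1
  a_of_s <- function(s) pi * radius_at(spec$radius, s)^2

  wt <- NULL
  if (length(spec$wedges)) {
    full <- sample_curve(spec$curve, ds = 0.02)
    wt <- purrr::map_dfr(seq_along(spec$wedges), function(i) {
      w <- spec$wedges[[i]]
      smid <- (w$s_start + w$s_end) / 2
      u <- apply_interp_rows(full$s, full$u, smid)
      v <- apply_interp_rows(full$s, full$v, smid)
      dir <- u * cos(w$theta_center_deg * pi / 180) +
        v * sin(w$theta_center_deg * pi / 180)
      tibble::tibble(
        wedge = i, arc_width_deg = w$arc_width_deg,
        thickness_mm = w$thickness_mm, extent_mm = w$s_end - w$s_start,
        gap_mm = w$gap_mm,
        orientation = classify_direction(dir, spec$side))
    })
  }

  sten <- list(s_c = NA_real_, max_local = NA_real_, severity = NA_character_,
               a_ref = NA_real_)
  if (length(spec$wedges)) {
    s_n <- min(vapply(spec$wedges, `[[`, numeric(1), "s_start"))
    s_m <- max(vapply(spec$wedges, `[[`, numeric(1), "s_end"))
    sgrid <- seq(0, s_n, length.out = 2001)
    a_ref <- max(a_of_s(sgrid))
    reg <- seq(s_n, s_m, length.out = 4001)
    a_reg <- a_of_s(reg)
    s_c <- (1 - mean(a_reg) / a_ref) * 100
    max_local <- (1 - min(a_reg) / a_ref) * 100
    sten <- list(s_c = s_c, max_local = max_local,
                 severity = severity_category(max_local), a_ref = a_ref)
  }

  structure(list(
    tortuosity_index = ti,
    total_length_mm = L,
    calc_count = length(spec$wedges),
    l_tot_mm = sum(vapply(spec$wedges, function(w) w$s_end - w$s_start,
                          numeric(1))),
    wedges = wt,
    lumen_area = a_of_s,
    cumulative_stenosis_percent = sten$s_c,
    max_local_stenosis_percent = sten$max_local,
    severity_category = sten$severity,
    a_ref_mm2 = sten$a_ref), class = "phantom_truth")
}

#' Stenosis severity category from the maximal local stenosis
#'
#' Categories use strict thresholds: a cross-section must exceed 30, 50, 70
#' or 90 percent stenosis for the artery to enter the next band.
#'
#' @param max_local_percent maximal per-slice stenosis (percent).
#' @return one of `"<30"`, `"30-50"`, `"50-70"`, `"70-90"`, `">90"`.
#' @export
severity_category <- function(max_local_percent) {
  if (is.na(max_local_percent)) return(NA_character_)
  if (max_local_percent > 90) ">90"
  else if (max_local_percent > 70) "70-90"
  else if (max_local_percent > 50) "50-70"
  else if (max_local_percent > 30) "30-50"
  else "<30"
}
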