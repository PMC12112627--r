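#' Build cross-sections perpendicular to the centerline
#'
#' One slice per centerline point (0.2 mm apart by default). The lumen
#' contour is the plane-mesh intersection loop containing the centerline
#' point; slices whose plane yields no such loop are flagged invalid and
#' excluded from measurement. Per slice, 360 radial rays (1 degree apart)
#' originate at the lumen centre (the area centroid of the contour); along
#' each ray the unsmoothed calcification mask is sampled at half-voxel
#' increments, giving the radial calcification intervals.
#'
#' @param lumen a lumen [tri_mesh()].
#' @param calc a calcification [binary_mask()] or `NULL`.
#' @param cl a `centerline` (already resampled to the slice spacing).
#' @param n_rays number of radial rays per slice (default 360).
#' @param reach_mm how far beyond the lumen boundary rays probe for
#'   calcification (mm).
#' @return An object of class `cross_sections`: list with `sections`
#'   (per-slice geometry) and `table` (a tibble: index, s_mm, valid,
#'   lumen_area_mm2, diameter_mm).
#' @export
generate_slices <- function(lumen, calc, cl, n_rays = 360L, reach_mm = 5) {
  stopifnot(inherits(lumen, "tri_mesh"), inherits(cl, "centerline"))
  if (!is.null(calc)) stopifnot(inherits(calc, "binary_mask"))
  n <- nrow(cl$points)
  th <- (seq_len(n_rays) - 1L) * (360 / n_rays) * pi / 180
  dr <- if (is.null(calc)) 0.15 else min(calc$spacing_mm) / 2
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    o <- cl$points[i, ]
    nv <- cl$tangent[i, ]
    uu <- cl$frame_u[i, ]
    vv <- cl$frame_v[i, ]
    loops <- mesh_plane_loops(lumen, o, nv, uu, vv)
    loop <- NULL
    for (lp in loops) {
      if (point_in_polygon(c(0, 0), lp)) { loop <- lp; break }
    }
    if (is.null(loop)) {
      sections[[i]] <- list(index = i, s_mm = cl$arclength[i], valid = FALSE)
      next
    }
    area <- polygon_area(loop)
    cen <- polygon_centroid(loop)
    lr <- polygon_ray_radii(loop, cen, th)
    calc_iv <- NULL
    ray_extent <- NULL
    ray_polar <- NULL
    if (!is.null(calc)) {
      r_max <- max(lr, na.rm = TRUE) + reach_mm
      radii <- seq(dr / 2, r_max, by = dr)
      ctr3 <- o + cen[1] * uu + cen[2] * vv
      dirs <- outer(cos(th), uu) + outer(sin(th), vv)
      vals <- sample_rays(calc, ctr3, dirs, radii)
      calc_iv <- intervals_from_samples(vals, radii, dr)
      # unthresholded radial integrals: mass-conserving under partial volume
      ray_extent <- as.numeric(vals %*% rep(dr, length(radii)))
      ray_polar <- as.numeric(vals %*% (radii * dr))
    }
    sections[[i]] <- list(
      index = i, s_mm = cl$arclength[i], valid = TRUE,
      origin = o, normal = nv, u = uu, v = vv,
      contour = loop, centroid = cen, area_mm2 = area,
      lumen_radius = lr, theta_deg = (seq_len(n_rays) - 1L) * (360 / n_rays),
      calc_intervals = calc_iv, ray_extent = ray_extent,
      ray_polar = ray_polar)
  }
  tab <- tibble::tibble(
    index = vapply(sections, `[[`, integer(1), "index"),
    s_mm = vapply(sections, `[[`, numeric(1), "s_mm"),
    valid = vapply(sections, `[[`, logical(1), "valid"),
    lumen_area_mm2 = vapply(sections, function(x)
      if (x$valid) x$area_mm2 else NA_real_, numeric(1)))
  tab$diameter_mm <- 2 * sqrt(tab$lumen_area_mm2 / pi)
  structure(list(sections = sections, table = tab, n_rays = n_rays),
            class = "cross_sections")
}

#' @export
print.cross_sections <- function(x, ...) {
  cat(sprintf("<cross_sections> %d slices (%d valid), spacing %.3g mm\n",
              nrow(x$table), sum(x$table$valid),
              mean(diff(x$table$s_mm))))
  invisible(x)
}

# Radius of a polygon boundary seen from an interior point, per angle.
# Uses polar interpolation of the polygon vertices (the lumen contour is
# star-shaped about its centroid for vessel cross-sections).
polygon_ray_radii <- function(poly, center, theta) {
  rel <- sweep(poly, 2, center, "-")
  a <- atan2(rel[, 2], rel[, 1])
  r <- sqrt(rowSums(rel^2))
  ord <- order(a)
  a <- a[ord]; r <- r[ord]
  a <- c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi)
  r <- c(r[length(r)], r, r[1])
  th <- ((theta + pi) %% (2 * pi)) - pi
  stats::approx(a, r, xout = th, rule = 2, ties = mean)$y
}

sample_rays <- function(mask, center, dirs, radii) {
  nr <- nrow(dirs)
  pts <- matrix(0, nr * length(radii), 3)
  for (k in seq_along(radii))
    pts[(k - 1L) * nr + seq_len(nr), ] <- sweep(dirs * radii[k], 2, center, "+")
  matrix(sample_volume(mask, pts, fill = 0), nr, length(radii))
}

# Runs of >= 0.5 samples along each ray become (r_in, r_out) intervals with
# linearly interpolated 0.5 crossings. Runs spanning a single sample
# (less than half a voxel radially) are partial-volume artifacts and are
# rejected: one voxel is the radial detection limit.
intervals_from_samples <- function(vals, radii, dr, min_run = 2L) {
  out <- vector("list", nrow(vals))
  for (j in seq_len(nrow(vals))) {
    v <- vals[j, ]
    inr <- v >= 0.5
    if (!any(inr)) next  # element stays NULL; assigning NULL would drop it
    rr <- rle(inr)
    ends <- cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1L
    ivs <- NULL
    for (q in which(rr$values & rr$lengths >= min_run)) {
      k1 <- starts[q]; k2 <- ends[q]
      r_in <- if (k1 == 1L) max(radii[1] - dr / 2, 0) else {
        f <- (0.5 - v[k1 - 1]) / (v[k1] - v[k1 - 1])
        radii[k1 - 1] + f * dr
      }
      r_out <- if (k2 == length(radii)) radii[k2] + dr / 2 else {
        f <- (v[k2] - 0.5) / (v[k2] - v[k2 + 1])
        radii[k2] + f * dr
      }
      ivs <- rbind(ivs, c(r_in, r_out))
    }
    out[[j]] <- ivs
  }
  out
}

#' Equivalent-circle lumen diameter of a cross-section
#'
#' Diameter of the circle with the same area as the lumen contour,
#' `2 * sqrt(area / pi)` — invariant under in-plane rotation.
#'
#' @param cs one element of `cross_sections$sections`.
#' @return diameter in mm (NA for invalid slices).
#' @export
lumen_diameter <- function(cs) {
  if (!isTRUE(cs$valid)) return(NA_real_)
  2 * sqrt(cs$area_mm2 / pi)
}

#' Per-slice calcification metrics
#'
#' Calcified rays are grouped into in-slice bodies by angular adjacency
#' (adjacent ray angles, wrapping at 359 -> 0). Per body: area by polar
#' patch quadrature (sum over member rays and intervals of radial extent x
#' mean radius x ray angular step); arc width as the inclusive count of
#' member ray angles (a single-ray body spans 1 degree at the default 360
#' rays); thickness as the largest single-interval radial extent; gap as
#' the mean over member rays of the innermost interval's clearance from the
#' lumen boundary, clamped at zero.
#'
#' @param cs one element of `cross_sections$sections`.
#' @return tibble with one row per in-slice body: `body_local_id`,
#'   `area_mm2`, `arc_width_deg`, `thickness_mm`, `gap_mm`, `theta_deg`
#'   (list column of member ray angles). Empty tibble when the slice has no
#'   calcification.
#' @export
measure_slice_calcifications <- function(cs) {
  empty <- tibble::tibble(body_local_id = integer(), area_mm2 = numeric(),
                          arc_width_deg = numeric(), thickness_mm = numeric(),
                          gap_mm = numeric(), theta_deg = list())
  if (!isTRUE(cs$valid) || is.null(cs$calc_intervals)) return(empty)
  has <- !vapply(cs$calc_intervals, is.null, logical(1))
  if (!any(has)) return(empty)
  n_rays <- length(cs$calc_intervals)
  step_deg <- 360 / n_rays
  groups <- group_circular(which(has), n_rays)
  rows <- lapply(seq_along(groups), function(g) {
    mem <- groups[[g]]
    area <- 0; thick <- 0
    gaps <- numeric(length(mem))
    exts <- numeric(length(mem))
    dth <- step_deg * pi / 180
    for (q in seq_along(mem)) {
      j <- mem[q]
      iv <- cs$calc_intervals[[j]]
      ext <- iv[, 2] - iv[, 1]
      thick <- max(thick, max(ext))
      gaps[q] <- max(0, min(iv[, 1]) - cs$lumen_radius[j])
      exts[q] <- sum(ext)
      # area: unthresholded polar integral when ray samples are available
      # (mass-conserving under partial volume), else the interval quadrature
      area <- area + if (!is.null(cs$ray_polar)) cs$ray_polar[j] * dth
                     else sum(ext * (iv[, 1] + iv[, 2]) / 2) * dth
    }
    # arc width: inclusive degree count with partial-volume edge weighting.
    # The two rays at each end of a run carry the half-voxel angular smear
    # of voxel sampling; they contribute fractionally by their radial extent
    # relative to the body's core (median) extent. Crisp intervals give
    # every ray weight 1, i.e. the plain inclusive count.
    wts <- rep(1, length(mem))
    if (length(mem) >= 3 && length(mem) < n_rays) {  # full rings have no edges
      core <- stats::median(exts)
      if (core > 0) {
        edge <- unique(c(1L, 2L, length(mem) - 1L, length(mem)))
        wts[edge] <- pmin(1, exts[edge] / core)
      }
    }
    tibble::tibble(body_local_id = g, area_mm2 = area,
                   arc_width_deg = sum(wts) * step_deg,
                   thickness_mm = thick, gap_mm = mean(gaps),
                   theta_deg = list(cs$theta_deg[mem]))
  })
  dplyr::bind_rows(rows)
}

# Group ray indices into runs adjacent modulo n (wrap-around at the seam).
group_circular <- function(idx, n) {
  if (!length(idx)) return(list())
  if (length(idx) == n) return(list(idx))
  present <- logical(n)
  present[idx] <- TRUE
  # break runs at gaps; rotate so a run does not straddle the seam
  gap_at <- which(!present)[1]
  ord <- ((seq_len(n) + gap_at - 1L) %% n) + 1L  # start scan just past a gap
  runs <- list()
  cur <- integer(0)
  for (j in ord) {
    if (present[j]) cur <- c(cur, j)
    else if (length(cur)) { runs[[length(runs) + 1L]] <- cur; cur <- integer(0) }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

#' Per-slice calcification table for a whole artery
#'
#' @param xs a `cross_sections` object.
#' @return tibble: one row per (slice, in-slice body).
#' @export
slice_calc_table <- function(xs) {
  rows <- lapply(xs$sections, function(cs) {
    m <- measure_slice_calcifications(cs)
    if (!nrow(m)) return(NULL)
    dplyr::mutate(m, index = cs$index, s_mm = cs$s_mm, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    out <- tibble::tibble(index = integer(), s_mm = numeric(),
                          body_local_id = integer(), area_mm2 = numeric(),
                          arc_width_deg = numeric(), thickness_mm = numeric(),
                          gap_mm = numeric(), theta_deg = list())
  out
}
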