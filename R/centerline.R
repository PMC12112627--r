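#' Centerline container
#'
#' An ordered 3D polyline with cumulative arclength, unit tangents,
#' transported in-plane frames (rotation-minimizing, so the frame never
#' flips on straight or inflected runs) and curvature.
#'
#' @param points K x 3 matrix of mm world coordinates.
#' @param curvature_sigma_mm Gaussian smoothing bandwidth (mm) applied to
#'   the curvature profile along arclength.
#' @return An object of class `centerline`.
#' @export
new_centerline <- function(points, curvature_sigma_mm = 2) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  d <- diff(points)
  seg <- sqrt(rowSums(d^2))
  if (any(seg <= 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    d <- diff(points)
    seg <- sqrt(rowSums(d^2))
  }
  s <- c(0, cumsum(seg))
  tangents <- tangents_of(points)
  fr <- transport_frames(points, tangents)
  curv <- polyline_curvature(points, s, curvature_sigma_mm)
  structure(list(points = points, arclength = s, tangent = tangents,
                 frame_u = fr$u, frame_v = fr$v, curvature = curv),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm, mean spacing %.4g mm\n",
              nrow(x$points), max(x$arclength),
              mean(diff(x$arclength))))
  invisible(x)
}

tangents_of <- function(points) {
  n <- nrow(points)
  t <- matrix(0, n, 3)
  t[1, ] <- points[2, ] - points[1, ]
  t[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2) t[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  t / sqrt(rowSums(t^2))
}

gaussian_smooth_profile <- function(x, s, sigma) {
  if (sigma <= 0 || length(x) < 3) return(x)
  step <- mean(diff(s))
  half <- max(1L, ceiling(3 * sigma / step))
  k <- exp(-0.5 * ((-half:half) * step / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
}

polyline_curvature <- function(points, s, sigma_mm) {
  n <- nrow(points)
  if (n < 3) return(rep(0, n))
  # circumscribed-circle curvature of point triples spaced ~sigma_mm apart:
  # a wide stencil keeps sub-voxel point jitter from swamping the signal
  h <- mean(diff(s))
  m <- max(1L, min(round(sigma_mm / h), (n - 1L) %/% 2L))
  k <- numeric(n)
  lo <- (1 + m):(n - m)
  a <- points[lo - m, , drop = FALSE]
  b <- points[lo, , drop = FALSE]
  cc <- points[lo + m, , drop = FALSE]
  ab <- b - a; bc <- cc - b; ac <- cc - a
  la <- sqrt(rowSums(ab^2)); lb <- sqrt(rowSums(bc^2)); lc <- sqrt(rowSums(ac^2))
  crossv <- cbind(ab[, 2] * bc[, 3] - ab[, 3] * bc[, 2],
                  ab[, 3] * bc[, 1] - ab[, 1] * bc[, 3],
                  ab[, 1] * bc[, 2] - ab[, 2] * bc[, 1])
  area2 <- sqrt(rowSums(crossv^2))
  denom <- la * lb * lc
  k[lo] <- ifelse(denom > 1e-12, 2 * area2 / denom, 0)
  k[seq_len(m)] <- k[m + 1L]
  k[(n - m + 1L):n] <- k[n - m]
  gaussian_smooth_profile(k, s, sigma_mm)
}

#' Resample a centerline at uniform arclength spacing
#'
#' Cross-sections are taken every `step` mm along the artery, so the
#' centerline is resampled to exactly `floor(L / step) + 1` points at that
#' spacing, with fresh tangents, transported frames and curvature.
#'
#' @param cl a [new_centerline()] object.
#' @param step spacing in mm (default 0.2).
#' @param curvature_sigma_mm see [new_centerline()].
#' @return a resampled `centerline`.
#' @export
resample_with_frames <- function(cl, step = 0.2, curvature_sigma_mm = 2) {
  if (step <= 0) stop("step must be positive")
  s <- cl$arclength
  L <- max(s)
  n <- floor(L / step + 1e-9) + 1L
  snew <- (seq_len(n) - 1L) * step
  pts <- vapply(1:3, function(j) stats::approx(s, cl$points[, j],
                                               xout = snew, rule = 2)$y,
                numeric(n))
  new_centerline(matrix(pts, n, 3), curvature_sigma_mm)
}

#' Tortuosity index of a centerline
#'
#' `TI = L / D - 1`, the arterial path length over the Euclidean distance of
#' its endpoints, minus one; 0 for a straight vessel. With
#' `exclude_petrous = TRUE` the index is computed on the C4-C6 sub-polyline
#' only, using that sub-polyline's own endpoints for `D`.
#'
#' @param cl a `centerline`.
#' @param labels a [label_bouthillier()] result (required when excluding the
#'   petrous segments).
#' @param exclude_petrous drop the petrous C2 and C3 segments first.
#' @return tortuosity index (dimensionless, >= 0).
#' @export
tortuosity_index <- function(cl, labels = NULL, exclude_petrous = FALSE) {
  pts <- cl$points
  s <- cl$arclength
  if (exclude_petrous) {
    if (is.null(labels)) stop("labels required to exclude the petrous segments")
    keep <- !(labels$label %in% c("C2", "C3"))
    if (sum(keep) < 2) stop("no non-petrous centerline points")
    pts <- pts[keep, , drop = FALSE]
    s <- s[keep]
  }
  L <- sum(sqrt(rowSums(diff(pts)^2)))
  D <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (D < 1e-9) stop("coincident endpoints: tortuosity undefined")
  L / D - 1
}

#' Extract a luminal centerline from a segmented lumen
#'
#' Three stages: (1) a voxel path between the endpoints through the lumen,
#' weighted toward the medial axis by the inverse squared distance-to-boundary
#' (Dijkstra on the 26-neighbourhood graph); (2) Gaussian smoothing of the
#' path coordinates; (3) fixed-point refinement moving every point to the
#' area centroid of its perpendicular lumen cross-section (tolerance
#' 0.05 mm), which enforces the lumen-centre semantics the radial rays rely
#' on.
#'
#' @param lumen a lumen [binary_mask()] (a [tri_mesh()] is accepted and
#'   voxelized internally at `mesh_voxel_mm`).
#' @param endpoints 2 x 3 matrix of world mm points inside the lumen.
#' @param step resampling step of the returned centerline (mm).
#' @param mesh_voxel_mm rasterization resolution for mesh input.
#' @param curvature_sigma_mm curvature smoothing bandwidth (mm).
#' @return a `centerline` resampled at `step` mm.
#' @export
extract_centerline <- function(lumen, endpoints, step = 0.2,
                               mesh_voxel_mm = 0.3, curvature_sigma_mm = 2) {
  if (inherits(lumen, "tri_mesh")) lumen <- mesh_to_mask(lumen, mesh_voxel_mm)
  stopifnot(inherits(lumen, "binary_mask"))
  endpoints <- rbind(endpoints)
  stopifnot(nrow(endpoints) == 2)
  d <- dim(lumen$values)
  eidx <- round(world_to_voxel(lumen, endpoints)) + 1
  for (i in 1:2) {
    ii <- eidx[i, ]
    if (any(ii < 1) || any(ii > d) || !lumen$values[ii[1], ii[2], ii[3]])
      stop(sprintf("endpoint %d is not inside the lumen", i))
  }
  dist_in <- .edt3d(!lumen$values, d, lumen$spacing_mm)  # distance to background
  eps <- min(lumen$spacing_mm) / 2
  cost <- array(Inf, d)
  cost[lumen$values] <- 1 / (dist_in[lumen$values] + eps)^2
  lin <- function(ii) (ii[3] - 1L) * d[1] * d[2] + (ii[2] - 1L) * d[1] + ii[1]
  path <- .dijkstra_grid(as.numeric(cost), d, lumen$spacing_mm,
                         lin(eidx[1, ]), lin(eidx[2, ]))
  if (!length(path)) stop("endpoints are not connected through the lumen")
  ai <- arrayInd(path, d)
  pts <- voxel_to_world(lumen, ai - 1)
  # pin the path to the supplied endpoints (the voxel path starts/ends at
  # the nearest voxel centre, up to half a voxel away)
  pts <- rbind(endpoints[1, ], pts, endpoints[2, ])
  # smooth voxel jitter, resample coarsely, then refine to centroids
  smooth_pinned <- function(p, s) {
    # smoothing with replicated ends pulls the extremes inward; the supplied
    # endpoints are trusted, so they are restored after each pass
    ends <- p[c(1, nrow(p)), ]
    for (j in 1:3) p[, j] <- gaussian_smooth_profile(p[, j], s, 1)
    p[c(1, nrow(p)), ] <- ends
    p
  }
  cl <- new_centerline(pts)
  cl <- resample_with_frames(cl, step = max(0.5, step))
  cl <- new_centerline(smooth_pinned(cl$points, cl$arclength))
  cl <- refine_to_centroids(cl, lumen)
  # light post-refinement smoothing: removes residual sub-voxel jitter that
  # would otherwise dominate curvature (corner cutting at vessel-scale bend
  # radii is well below voxel size)
  cl <- new_centerline(smooth_pinned(cl$points, cl$arclength))
  resample_with_frames(cl, step = step, curvature_sigma_mm = curvature_sigma_mm)
}

# Move each centerline point to the centroid of its perpendicular lumen
# cross-section (boundary traced along radial rays through the mask).
refine_to_centroids <- function(cl, lumen, n_rays = 48L, max_iter = 10L,
                                tol = 0.05) {
  r_max <- max(dim(lumen$values) * lumen$spacing_mm) / 2
  dr <- min(lumen$spacing_mm) / 2
  radii <- seq(dr, r_max, by = dr)
  th <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  for (it in seq_len(max_iter)) {
    n <- nrow(cl$points)
    moved <- 0
    newpts <- cl$points
    # endpoints stay where supplied; refining them with one-sided tangent
    # estimates is unstable near the end caps
    for (i in seq(2L, n - 1L)) {
      ctr <- cl$points[i, ]
      dirs <- outer(cos(th), cl$frame_u[i, ]) + outer(sin(th), cl$frame_v[i, ])
      rb <- ray_boundary(lumen, ctr, dirs, radii)
      ok <- is.finite(rb)
      if (sum(ok) < n_rays / 2) next
      rb[!ok] <- stats::median(rb[ok])
      poly <- cbind(rb * cos(th), rb * sin(th))
      cen2 <- polygon_centroid(poly)
      step_len <- sqrt(sum(cen2^2))
      # clamp: large apparent moves come from tilted-plane artifacts, but a
      # bounded step in that direction still converges for honest offsets
      if (step_len > 1) cen2 <- cen2 / step_len
      newpts[i, ] <- ctr + cen2[1] * cl$frame_u[i, ] + cen2[2] * cl$frame_v[i, ]
      moved <- max(moved, min(step_len, 1))
    }
    cl <- new_centerline(newpts)
    if (moved < tol) break
  }
  cl
}

# First outward 0.5-crossing of the interpolated mask along each ray.
ray_boundary <- function(mask, center, dirs, radii) {
  nr <- nrow(dirs)
  pts <- matrix(0, nr * length(radii), 3)
  for (k in seq_along(radii))
    pts[(k - 1L) * nr + seq_len(nr), ] <-
      sweep(dirs * radii[k], 2, center, "+")
  vals <- sample_volume(mask, pts, fill = 0)
  vals <- matrix(vals, nr, length(radii))
  out <- rep(NA_real_, nr)
  for (j in seq_len(nr)) {
    v <- vals[j, ]
    below <- which(v < 0.5)
    if (!length(below)) next
    k <- below[1]
    if (k == 1L) { out[j] <- radii[1] / 2; next }
    # linear interpolation of the 0.5 crossing between samples k-1 and k
    f <- (v[k - 1] - 0.5) / (v[k - 1] - v[k])
    out[j] <- radii[k - 1] + f * (radii[k] - radii[k - 1])
  }
  out
}

# Rasterize a closed mesh into a binary mask by per-slice polygon filling.
mesh_to_mask <- function(mesh, voxel_mm = 0.3, role = mesh$role) {
  lo <- apply(mesh$vertices, 2, min) - 2 * voxel_mm
  hi <- apply(mesh$vertices, 2, max) + 2 * voxel_mm
  dims <- as.integer(ceiling((hi - lo) / voxel_mm)) + 1L
  vals <- array(FALSE, dims)
  xs <- lo[1] + (seq_len(dims[1]) - 1) * voxel_mm
  ys <- lo[2] + (seq_len(dims[2]) - 1) * voxel_mm
  grid <- cbind(rep(xs, times = dims[2]), rep(ys, each = dims[1]))
  for (k in seq_len(dims[3])) {
    z <- lo[3] + (k - 1) * voxel_mm
    loops <- mesh_plane_loops(mesh, c(0, 0, z), c(0, 0, 1),
                              c(1, 0, 0), c(0, 1, 0))
    if (!length(loops)) next
    inside <- rep(FALSE, nrow(grid))
    for (lp in loops)
      inside <- xor(inside, points_in_polygon(grid, lp))
    vals[, , k] <- inside
  }
  binary_mask(vals, voxel_mm, lo, role = role)
}

# Vectorized even-odd point-in-polygon test.
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (i in seq_len(n)) {
    cond <- ((y[i] > py) != (yj[i] > py))
    if (any(cond)) {
      xint <- (xj[i] - x[i]) * (py[cond] - y[i]) / (yj[i] - y[i]) + x[i]
      hit <- px[cond] < xint
      inside[cond] <- xor(inside[cond], hit)
    }
  }
  inside
}

#' Label Bouthillier C2-C6 sections from local curvature
#'
#' The four section boundaries (C2/C3 petrous genu, C3/C4 lacerum bend,
#' C4/C5 posterior genu, C5/C6 anterior genu) are placed at the four most
#' prominent peaks of the smoothed curvature profile, in arclength order
#' from the proximal (petrous-canal) end. When fewer than four prominent
#' peaks exist (e.g. a straight tube), boundaries fall back to fixed
#' arclength fractions and the result carries `fallback = TRUE`.
#'
#' @param cl a `centerline` running proximal (petrous) to distal.
#' @param sigma_mm Gaussian smoothing of the curvature before peak picking.
#' @param min_peak_curvature peaks below this curvature (1/mm) are ignored.
#' @param min_separation_mm minimum arclength between accepted peaks.
#' @param boundary_fractions fallback boundary positions as fractions of the
#'   total length.
#' @param boundary_overrides_mm optional explicit boundary arclengths
#'   (length 4, increasing) that bypass peak picking entirely.
#' @return list of class `segment_labels`: `label` (factor per point,
#'   C2-C6), `petrous` (logical per point), `boundaries_mm`, `fallback`.
#' @export
label_bouthillier <- function(cl, sigma_mm = 2, min_peak_curvature = 0.05,
                              min_separation_mm = 4,
                              boundary_fractions = c(0.25, 0.40, 0.60, 0.80),
                              boundary_overrides_mm = NULL) {
  s <- cl$arclength
  L <- max(s)
  fallback <- FALSE
  if (!is.null(boundary_overrides_mm)) {
    stopifnot(length(boundary_overrides_mm) == 4,
              !is.unsorted(boundary_overrides_mm))
    bounds <- boundary_overrides_mm
  } else {
    k <- gaussian_smooth_profile(cl$curvature, s, sigma_mm)
    peaks <- find_peaks(k, s, min_peak_curvature, min_separation_mm)
    if (length(peaks) >= 4) {
      top <- peaks[order(-k[peaks])][1:4]
      bounds <- sort(s[top])
    } else {
      fallback <- TRUE
      bounds <- boundary_fractions * L
    }
  }
  seg_names <- c("C2", "C3", "C4", "C5", "C6")
  idx <- findInterval(s, bounds) + 1L
  label <- factor(seg_names[idx], levels = seg_names)
  structure(list(label = label, petrous = label %in% c("C2", "C3"),
                 boundaries_mm = bounds, fallback = fallback),
            class = "segment_labels")
}

find_peaks <- function(k, s, min_height, min_sep) {
  n <- length(k)
  if (n < 3) return(integer(0))
  cand <- which(k[2:(n - 1)] >= k[1:(n - 2)] &
                k[2:(n - 1)] >= k[3:n]) + 1L
  cand <- cand[k[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-k[cand])]
  keep <- integer(0)
  for (p in cand) {
    if (all(abs(s[p] - s[keep]) >= min_sep)) keep <- c(keep, p)
  }
  sort(keep)
}
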