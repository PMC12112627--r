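#' Parametric centerline curves for vessel phantoms
#'
#' Curve specifications with closed-form arclength. Four kinds are supported:
#' a straight line, a circular arc, a helix, and `siphon_composite` — a
#' C1-continuous chain of straight and arc pieces emulating the bends of the
#' carotid siphon, with the junction arclengths known by construction.
#'
#' @param length_mm curve length in mm (line, helix).
#' @return An object of class `curve_spec`.
#' @name curve_spec
NULL

new_curve <- function(kind, length_mm, params) {
  stopifnot(length_mm > 0)
  structure(list(kind = kind, length_mm = length_mm, params = params),
            class = "curve_spec")
}

#' @rdname curve_spec
#' @param direction unit direction of the line (default +z).
#' @export
curve_line <- function(length_mm, direction = c(0, 0, 1)) {
  direction <- direction / sqrt(sum(direction^2))
  new_curve("line", length_mm, list(direction = direction))
}

#' @rdname curve_spec
#' @param arc_radius_mm radius of the circular arc.
#' @param sweep_deg swept angle in degrees (180 = semicircle).
#' @export
curve_arc <- function(arc_radius_mm, sweep_deg) {
  stopifnot(arc_radius_mm > 0, sweep_deg > 0, sweep_deg <= 360)
  new_curve("circular_arc", arc_radius_mm * sweep_deg * pi / 180,
            list(R = arc_radius_mm, sweep_deg = sweep_deg))
}

#' @rdname curve_spec
#' @param helix_radius_mm,pitch_mm helix radius and rise per full turn.
#' @export
curve_helix <- function(helix_radius_mm, pitch_mm, length_mm) {
  stopifnot(helix_radius_mm > 0, pitch_mm > 0)
  new_curve("helix", length_mm,
            list(a = helix_radius_mm, pitch = pitch_mm))
}

#' @rdname curve_spec
#' @param segments list of pieces, each `list(type = "line", length = mm)` or
#'   `list(type = "arc", radius = mm, sweep_deg = deg, roll_deg = deg)`;
#'   `roll_deg` rotates the bending plane about the running tangent before
#'   the arc (0 keeps bending in the current normal plane).
#' @export
curve_siphon <- function(segments) {
  lens <- vapply(segments, function(sg) {
    if (sg$type == "line") sg$length
    else sg$radius * sg$sweep_deg * pi / 180
  }, numeric(1))
  new_curve("siphon_composite", sum(lens),
            list(segments = segments, seg_lengths = lens,
                 junctions_mm = cumsum(lens)[-length(lens)]))
}

#' A carotid-siphon-like composite curve with known bend arclengths
#'
#' A C1 chain of straight runs and circular bends emulating the course of
#' the intracranial ICA from the petrous canal to the distal siphon: an
#' ascending petrous run, the petrous genu, the horizontal petrous run, the
#' lacerum bend (out of plane), and the posterior and anterior genua of the
#' siphon. The four bend midpoints — the anatomical C2/C3, C3/C4, C4/C5 and
#' C5/C6 boundaries — are returned as an attribute.
#'
#' @param scale overall scale factor (1 = adult-sized, ~72 mm).
#' @return a [curve_siphon()] spec with attribute `boundaries_mm`.
#' @export
carotid_siphon_curve <- function(scale = 1) {
  segs <- list(
    list(type = "line", length = 12 * scale),
    list(type = "arc", radius = 5 * scale, sweep_deg = 75),
    list(type = "line", length = 12 * scale),
    list(type = "arc", radius = 5 * scale, sweep_deg = 70, roll_deg = 90),
    list(type = "line", length = 6 * scale),
    list(type = "arc", radius = 4 * scale, sweep_deg = 110, roll_deg = 10),
    list(type = "line", length = 5 * scale),
    list(type = "arc", radius = 4 * scale, sweep_deg = 120, roll_deg = 20),
    list(type = "line", length = 8 * scale))
  cv <- curve_siphon(segs)
  lens <- cv$params$seg_lengths
  cum <- c(0, cumsum(lens))
  # boundaries at the bend midpoints (segments 2, 4, 6, 8)
  attr(cv, "boundaries_mm") <- cum[c(2, 4, 6, 8)] + lens[c(2, 4, 6, 8)] / 2
  cv
}

rodrigues <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Evaluate a curve at given arclengths
#'
#' @param curve a [curve_spec].
#' @param s numeric vector of arclengths in `[0, length_mm]`.
#' @return list with `points` (N x 3) and `tangents` (N x 3, unit).
#' @export
curve_eval <- function(curve, s) {
  s <- pmin(pmax(s, 0), curve$length_mm)
  p <- curve$params
  switch(curve$kind,
    line = {
      pts <- outer(s, p$direction)
      list(points = pts, tangents = matrix(p$direction, length(s), 3,
                                           byrow = TRUE))
    },
    circular_arc = {
      # circle of radius R in the x-z plane, starting at origin heading +z
      u <- s / p$R
      pts <- cbind(p$R * (1 - cos(u)), 0, p$R * sin(u))
      tg <- cbind(sin(u), 0, cos(u))
      list(points = pts, tangents = tg)
    },
    helix = {
      cfac <- sqrt(p$a^2 + (p$pitch / (2 * pi))^2)
      t <- s / cfac
      pts <- cbind(p$a * cos(t) - p$a, p$a * sin(t), p$pitch * t / (2 * pi))
      tg <- cbind(-p$a * sin(t), p$a * cos(t), p$pitch / (2 * pi)) / cfac
      list(points = pts, tangents = tg)
    },
    siphon_composite = eval_composite(curve, s),
    stop("unknown curve kind")
  )
}

eval_composite <- function(curve, s) {
  segs <- curve$params$segments
  lens <- curve$params$seg_lengths
  # frame state at the start of each segment
  starts <- vector("list", length(segs) + 1L)
  starts[[1]] <- list(p = c(0, 0, 0), t = c(0, 0, 1), n = c(1, 0, 0))
  for (i in seq_along(segs)) {
    st <- starts[[i]]
    sg <- segs[[i]]
    if (sg$type == "line") {
      starts[[i + 1]] <- list(p = st$p + sg$length * st$t, t = st$t, n = st$n)
    } else {
      roll <- if (is.null(sg$roll_deg)) 0 else sg$roll_deg * pi / 180
      b <- pracma_cross(st$t, st$n)
      d <- cos(roll) * st$n + sin(roll) * b     # unit vector toward arc centre
      alpha <- sg$sweep_deg * pi / 180
      axis <- pracma_cross(st$t, d)
      ctr <- st$p + sg$radius * d
      pend <- ctr - sg$radius * (cos(alpha) * d - sin(alpha) * st$t)
      tend <- rodrigues(st$t, axis, alpha)
      nend <- rodrigues(st$n, axis, alpha)
      starts[[i + 1]] <- list(p = pend, t = tend / sqrt(sum(tend^2)),
                              n = nend / sqrt(sum(nend^2)))
    }
  }
  cum <- c(0, cumsum(lens))
  pts <- matrix(0, length(s), 3)
  tg <- matrix(0, length(s), 3)
  seg_of <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
                 length(segs))
  for (i in seq_along(s)) {
    k <- seg_of[i]
    st <- starts[[k]]
    sg <- segs[[k]]
    ds <- s[i] - cum[k]
    if (sg$type == "line") {
      pts[i, ] <- st$p + ds * st$t
      tg[i, ] <- st$t
    } else {
      roll <- if (is.null(sg$roll_deg)) 0 else sg$roll_deg * pi / 180
      b <- pracma_cross(st$t, st$n)
      d <- cos(roll) * st$n + sin(roll) * b
      u <- ds / sg$radius
      ctr <- st$p + sg$radius * d
      pts[i, ] <- ctr - sg$radius * (cos(u) * d - sin(u) * st$t)
      tg[i, ] <- cos(u) * st$t + sin(u) * d
    }
  }
  list(points = pts, tangents = tg)
}

#' Rotation-minimizing frames along a polyline (double-reflection)
#'
#' Transports an in-plane frame `(u, v)` along a sampled curve with minimal
#' twist about the tangent. Used both when planting calcified wedges at known
#' angular positions and when measuring angular positions on extracted
#' centerlines; angles measured in these frames are comparable because the
#' classification into world orientation classes uses the world direction of
#' each ray, not the frame itself.
#'
#' @param points,tangents N x 3 point and unit-tangent matrices.
#' @param u0 optional initial in-plane axis (unit, orthogonal to first
#'   tangent); default derived from the world x axis.
#' @return list with `u`, `v`: N x 3 unit in-plane axes.
#' @export
transport_frames <- function(points, tangents, u0 = NULL) {
  n <- nrow(points)
  u <- matrix(0, n, 3)
  if (is.null(u0)) {
    t1 <- tangents[1, ]
    ref <- c(1, 0, 0)
    if (abs(sum(ref * t1)) > 0.9) ref <- c(0, 1, 0)
    u0 <- ref - sum(ref * t1) * t1
  }
  u[1, ] <- u0 / sqrt(sum(u0^2))
  for (i in seq_len(n - 1)) {
    # double reflection (Wang et al. rotation minimizing frames)
    v1 <- points[i + 1, ] - points[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-20) { u[i + 1, ] <- u[i, ]; next }
    uL <- u[i, ] - (2 / c1) * sum(v1 * u[i, ]) * v1
    tL <- tangents[i, ] - (2 / c1) * sum(v1 * tangents[i, ]) * v1
    v2 <- tangents[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    ui <- if (c2 < 1e-20) uL else uL - (2 / c2) * sum(v2 * uL) * v2
    ui <- ui - sum(ui * tangents[i + 1, ]) * tangents[i + 1, ]
    u[i + 1, ] <- ui / sqrt(sum(ui^2))
  }
  v <- cbind(tangents[, 2] * u[, 3] - tangents[, 3] * u[, 2],
             tangents[, 3] * u[, 1] - tangents[, 1] * u[, 3],
             tangents[, 1] * u[, 2] - tangents[, 2] * u[, 1])
  list(u = u, v = v)
}

#' Densely sample a curve with transported frames
#'
#' @param curve a [curve_spec].
#' @param ds sample spacing in mm.
#' @return list: `s`, `points`, `tangents`, `u`, `v`.
#' @export
sample_curve <- function(curve, ds = 0.05) {
  n <- max(2L, ceiling(curve$length_mm / ds) + 1L)
  s <- seq(0, curve$length_mm, length.out = n)
  ev <- curve_eval(curve, s)
  fr <- transport_frames(ev$points, ev$tangents)
  list(s = s, points = ev$points, tangents = ev$tangents, u = fr$u, v = fr$v)
}
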