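#' Group calcification into 3D bodies and map in-slice bodies onto them
#'
#' Individual calcifications are the 26-connected components of the
#' calcification mask (26-connectivity keeps voxelized thin shells intact).
#' Every in-slice body from [slice_calc_table()] is assigned to the 3D
#' component found at a representative ray point inside it.
#'
#' @param xs a `cross_sections` object.
#' @param calc the calcification [binary_mask()].
#' @return list of class `calc_bodies`: `slice_bodies` (the per-slice table
#'   with a `body` column), `bodies` (per-body tibble: `body`, `n_slices`,
#'   `s_min`, `s_max`, `burden_mm2`), `label_volume`.
#' @export
connect_bodies <- function(xs, calc) {
  stopifnot(inherits(xs, "cross_sections"), inherits(calc, "binary_mask"))
  lab <- .label_components(calc$values, dim(calc$values), 26L)
  st <- slice_calc_table(xs)
  if (nrow(st)) {
    body <- integer(nrow(st))
    for (r in seq_len(nrow(st))) {
      cs <- xs$sections[[st$index[r]]]
      th <- st$theta_deg[[r]]
      lbs <- integer(0)
      for (t in th) {
        j <- which(abs(cs$theta_deg - t) < 1e-9)[1]
        iv <- cs$calc_intervals[[j]]
        rmid <- (iv[, 1] + iv[, 2]) / 2
        dir <- cos(t * pi / 180) * cs$u + sin(t * pi / 180) * cs$v
        ctr <- cs$origin + cs$centroid[1] * cs$u + cs$centroid[2] * cs$v
        pts <- sweep(outer(rmid, dir), 2, ctr, "+")
        vidx <- round(world_to_voxel(calc, pts)) + 1
        d <- dim(lab)
        ok <- vidx[, 1] >= 1 & vidx[, 1] <= d[1] &
              vidx[, 2] >= 1 & vidx[, 2] <= d[2] &
              vidx[, 3] >= 1 & vidx[, 3] <= d[3]
        if (any(ok)) {
          li <- lab[vidx[ok, , drop = FALSE]]
          lbs <- c(lbs, li[li > 0])
        }
      }
      body[r] <- if (length(lbs)) as.integer(names(which.max(table(lbs))))
                 else NA_integer_
    }
    st$body <- body
  } else {
    st$body <- integer(0)
  }
  present <- sort(unique(st$body[!is.na(st$body)]))
  bodies <- if (length(present)) {
    dplyr::summarise(
      dplyr::group_by(st[!is.na(st$body), ], .data$body),
      n_slices = dplyr::n_distinct(.data$index),
      s_min = min(.data$s_mm), s_max = max(.data$s_mm),
      burden_mm2 = sum(.data$area_mm2), .groups = "drop")
  } else {
    tibble::tibble(body = integer(), n_slices = integer(),
                   s_min = numeric(), s_max = numeric(),
                   burden_mm2 = numeric())
  }
  structure(list(slice_bodies = st, bodies = bodies, label_volume = lab),
            class = "calc_bodies")
}

#' Longitudinal extent of calcifications
#'
#' Per body, the extent `L_j` is the sum of arclength gaps between
#' consecutive member slices — `0.2 * (n - 1)` mm for a body present on `n`
#' contiguous slices, and 0 for a single-slice body. The total longitudinal
#' extent `L_TOT` is the sum of the per-body extents.
#'
#' @param cb a `calc_bodies` object.
#' @return list: `per_body` (tibble `body`, `l_j_mm`), `l_tot_mm`.
#' @export
longitudinal_extent <- function(cb) {
  st <- cb$slice_bodies
  st <- st[!is.na(st$body), ]
  per <- dplyr::summarise(
    dplyr::group_by(st, .data$body),
    l_j_mm = {
      ss <- sort(unique(.data$s_mm))
      if (length(ss) < 2) 0 else sum(diff(ss))
    },
    .groups = "drop")
  list(per_body = per, l_tot_mm = sum(per$l_j_mm))
}

#' Lumen surface area in contact with calcification
#'
#' Sum of lumen triangle areas whose centroid lies within `contact_mm` of a
#' calcified voxel centre. The default distance is two-thirds of the voxel
#' spacing: it covers the half-voxel offset a boundary voxel's centre can
#' have from a surface the voxel touches, while excluding the next voxel
#' shell, so the contact patch neither leaks sideways nor misses adjacent
#' calcification.
#'
#' @param lumen a lumen [tri_mesh()].
#' @param calc the calcification [binary_mask()].
#' @param contact_mm contact distance in mm; `NULL` uses 2/3 of the mean
#'   voxel spacing.
#' @return contact area in mm^2.
#' @export
surface_contact <- function(lumen, calc, contact_mm = NULL) {
  stopifnot(inherits(lumen, "tri_mesh"), inherits(calc, "binary_mask"))
  if (!any(calc$values)) return(0)
  if (is.null(contact_mm)) contact_mm <- 2 / 3 * mean(calc$spacing_mm)
  dmap <- distance_to_mask(calc)
  cen <- face_centroids(lumen)
  dd <- sample_volume(dmap, cen, fill = Inf)
  sum(face_areas(lumen)[dd <= contact_mm])
}

#' Calcification-attributable stenosis
#'
#' For each contiguous run of calcified slices, the reference area `A_ref`
#' is the largest lumen area on slices strictly proximal to the run's first
#' calcified slice (when no proximal slice exists the first slice itself is
#' used and the result is flagged). Per slice, `s_i = (1 - A_i / A_ref) *
#' 100`. The cumulative stenosis of a region spanning slices `N..M` divides
#' by `M - N` reference areas, so it is computed over the matching count of
#' slices and equals the mean of `s_i` over that same slice set exactly.
#' Severity is the highest of the 30 / 50 / 70 / 90 percent thresholds
#' strictly exceeded by any calcified slice.
#'
#' @param xs a `cross_sections` object.
#' @param cb a `calc_bodies` object for the same artery.
#' @return list of class `stenosis_result`: `regions` (tibble: `region`,
#'   `first`, `last`, `ref_index`, `a_ref_mm2`, `s_c_percent`,
#'   `max_local_percent`, `no_proximal_flag`), `per_slice` (tibble: `index`,
#'   `s_mm`, `region`, `a_mm2`, `s_i_percent`), `max_cumulative_percent`,
#'   `max_local_percent`, `severity`.
#' @export
stenosis <- function(xs, cb) {
  tab <- xs$table
  calcified <- sort(unique(cb$slice_bodies$index))
  if (!length(calcified)) stop("no calcified slice: stenosis undefined")
  runs <- split(calcified, cumsum(c(1, diff(calcified) != 1)))
  regions <- list()
  per_slice <- list()
  for (g in seq_along(runs)) {
    r <- runs[[g]]
    N <- min(r); M <- max(r)
    prox <- tab[tab$valid & tab$index < N, ]
    flag <- FALSE
    if (nrow(prox)) {
      ref_index <- prox$index[which.max(prox$lumen_area_mm2)]
      a_ref <- max(prox$lumen_area_mm2)
    } else {
      ref_index <- tab$index[tab$valid][1]
      a_ref <- tab$lumen_area_mm2[tab$index == ref_index]
      flag <- TRUE
    }
    reg <- tab[tab$index >= N & tab$index <= M & tab$valid, ]
    s_i <- (1 - reg$lumen_area_mm2 / a_ref) * 100
    # formula slice set: M - N slices (the printed denominator); a
    # single-slice region uses that one slice
    count <- max(M - N, 1L)
    in_formula <- reg$index < N + count
    s_c <- (1 - sum(reg$lumen_area_mm2[in_formula]) / (a_ref * count)) * 100
    regions[[g]] <- tibble::tibble(
      region = g, first = N, last = M, ref_index = ref_index,
      a_ref_mm2 = a_ref, s_c_percent = s_c,
      max_local_percent = max(s_i), no_proximal_flag = flag)
    per_slice[[g]] <- tibble::tibble(
      index = reg$index, s_mm = reg$s_mm, region = g,
      a_mm2 = reg$lumen_area_mm2, s_i_percent = s_i,
      in_formula_set = in_formula)
  }
  regions <- dplyr::bind_rows(regions)
  per_slice <- dplyr::bind_rows(per_slice)
  max_local <- max(per_slice$s_i_percent)
  structure(list(regions = regions, per_slice = per_slice,
                 max_cumulative_percent = max(regions$s_c_percent),
                 max_local_percent = max_local,
                 severity = severity_category(max_local)),
            class = "stenosis_result")
}

#' Predominant Bouthillier segment of the calcification burden
#'
#' Sums in-slice calcification area per labelled segment; returns the
#' segment with the largest burden. Exact ties break toward the more distal
#' segment, with `tie = TRUE` in the attributes.
#'
#' @param cb a `calc_bodies` object.
#' @param labels a `segment_labels` object on the same centerline.
#' @return the segment name (`"C2"`..`"C6"`), with attributes `burden`
#'   (named numeric) and `tie`.
#' @export
predominant_segment <- function(cb, labels) {
  st <- cb$slice_bodies
  if (!nrow(st)) stop("no calcification: predominant segment undefined")
  seg <- as.character(labels$label[st$index])
  burden <- tapply(st$area_mm2, factor(seg, levels = levels(labels$label)),
                   sum, default = 0)
  burden[is.na(burden)] <- 0
  best <- max(burden)
  cand <- which(burden == best)
  pick <- names(burden)[max(cand)]  # distal = higher segment number
  structure(pick, burden = burden, tie = length(cand) > 1)
}

#' Predominant spatial orientation of the calcification burden
#'
#' Every calcified ray contributes its polar-patch area to one of four wall
#' classes by the world direction of the ray: medial / lateral (patient x
#' axis, signed by artery side) and anteroinferior / posterosuperior (45
#' degree composite directions in the sagittal plane). The class holding
#' the largest share of the burden is returned.
#'
#' @param xs a `cross_sections` object.
#' @param side `"left"` or `"right"` ICA.
#' @return the class name, with attribute `burden` (named numeric).
#' @export
predominant_orientation <- function(xs, side = c("left", "right")) {
  side <- match.arg(side)
  classes <- names(orientation_classes(side))
  burden <- stats::setNames(numeric(4), classes)
  n_rays <- xs$n_rays
  dth <- (360 / n_rays) * pi / 180
  for (cs in xs$sections) {
    if (!isTRUE(cs$valid) || is.null(cs$calc_intervals)) next
    has <- which(!vapply(cs$calc_intervals, is.null, logical(1)))
    if (!length(has)) next
    th <- cs$theta_deg[has] * pi / 180
    dirs <- outer(cos(th), cs$u) + outer(sin(th), cs$v)
    cls <- classify_direction(dirs, side)
    w <- vapply(has, function(j) {
      iv <- cs$calc_intervals[[j]]
      sum((iv[, 2] - iv[, 1]) * (iv[, 1] + iv[, 2]) / 2) * dth
    }, numeric(1))
    for (k in seq_along(has))
      burden[cls[k]] <- burden[cls[k]] + w[k]
  }
  if (all(burden == 0)) stop("no calcification: orientation undefined")
  pick <- classes[max(which(burden == max(burden)))]
  structure(pick, burden = burden)
}

#' Aggregate all measurements into one artery record
#'
#' Mean-type calcification fields average over calcified slices pooling all
#' bodies; lumen diameter statistics run over all valid slices; max-type
#' fields are maxima over the same domains. Arteries without calcification
#' keep their lumen fields and carry NA calcification fields.
#'
#' @param xs a `cross_sections` object.
#' @param cl the `centerline`.
#' @param labels a `segment_labels` object.
#' @param cb a `calc_bodies` object (or NULL when no calcification).
#' @param lumen the lumen [tri_mesh()].
#' @param calc the calcification [binary_mask()] (or NULL).
#' @param side `"left"` or `"right"`.
#' @param contact_mm see [surface_contact()].
#' @param edge_trim_mm arclength trimmed from both ends for lumen diameter
#'   statistics (the end slices cut across the artificial cap planes of the
#'   analyzed range).
#' @return a one-row tibble of class `artery_morphometry`.
#' @export
aggregate_artery <- function(xs, cl, labels, cb, lumen, calc,
                             side = c("left", "right"), contact_mm = NULL,
                             edge_trim_mm = 1) {
  side <- match.arg(side)
  tab <- xs$table[xs$table$valid, ]
  # the first/last slices cut across the artificial end caps of the analyzed
  # range; they are excluded from lumen diameter statistics
  L <- max(cl$arclength)
  tab <- tab[tab$s_mm >= edge_trim_mm & tab$s_mm <= L - edge_trim_mm, ]
  out <- tibble::tibble(
    side = side,
    min_lumen_diameter_mm = min(tab$diameter_mm),
    mean_lumen_diameter_mm = mean(tab$diameter_mm),
    max_lumen_diameter_mm = max(tab$diameter_mm),
    total_length_mm = max(cl$arclength),
    tortuosity_index = tortuosity_index(cl),
    nonpetrous_tortuosity_index =
      tortuosity_index(cl, labels, exclude_petrous = TRUE))
  has_calc <- !is.null(cb) && nrow(cb$slice_bodies) > 0
  if (has_calc) {
    st <- cb$slice_bodies
    ext <- longitudinal_extent(cb)
    sten <- stenosis(xs, cb)
    out <- dplyr::mutate(
      out,
      calc_count = nrow(cb$bodies),
      l_tot_mm = ext$l_tot_mm,
      surface_contact_mm2 = surface_contact(lumen, calc, contact_mm),
      mean_gap_mm = mean(st$gap_mm),
      max_calc_area_mm2 = max(st$area_mm2),
      mean_calc_area_mm2 = mean(st$area_mm2),
      max_arc_width_deg = max(st$arc_width_deg),
      mean_arc_width_deg = mean(st$arc_width_deg),
      max_thickness_mm = max(st$thickness_mm),
      mean_thickness_mm = mean(st$thickness_mm),
      max_cumulative_stenosis_percent = sten$max_cumulative_percent,
      max_local_stenosis_percent = sten$max_local_percent,
      stenosis_severity = sten$severity,
      predominant_segment = as.character(predominant_segment(cb, labels)),
      predominant_orientation = as.character(predominant_orientation(xs, side)))
  } else {
    out <- dplyr::mutate(
      out, calc_count = 0L, l_tot_mm = NA_real_,
      surface_contact_mm2 = NA_real_, mean_gap_mm = NA_real_,
      max_calc_area_mm2 = NA_real_, mean_calc_area_mm2 = NA_real_,
      max_arc_width_deg = NA_real_, mean_arc_width_deg = NA_real_,
      max_thickness_mm = NA_real_, mean_thickness_mm = NA_real_,
      max_cumulative_stenosis_percent = NA_real_,
      max_local_stenosis_percent = NA_real_,
      stenosis_severity = NA_character_,
      predominant_segment = NA_character_,
      predominant_orientation = NA_character_)
  }
  class(out) <- c("artery_morphometry", class(out))
  out
}
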