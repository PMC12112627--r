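#' Segment the contrast-filled lumen by HU window
#'
#' Voxels whose Hounsfield value falls inside `[lo, hi]` (inclusive; default
#' 100-600 HU, the window separating intra-arterial contrast from soft
#' tissue and calcification) become lumen. When seed points are given, the
#' mask is restricted to the region grown from the seeds inside the window,
#' emulating seeded region growing with a bounded number of dilation rounds.
#'
#' @param vol an [hu_volume()].
#' @param lo,hi inclusive HU window bounds (`lo < hi`).
#' @param seeds optional N x 3 matrix of world mm seed points; each must fall
#'   inside the HU window.
#' @param iterations maximum dilation rounds for seeded growth (each round
#'   expands one 26-neighbourhood step).
#' @return a lumen [binary_mask()].
#' @export
threshold_lumen <- function(vol, lo = 100, hi = 600, seeds = NULL,
                            iterations = 25L) {
  stopifnot(inherits(vol, "hu_volume"), lo < hi)
  inwin <- vol$values >= lo & vol$values <= hi
  if (!is.null(seeds)) {
    seeds <- rbind(seeds)
    sidx <- round(world_to_voxel(vol, seeds))
    d <- dim(vol$values)
    for (i in seq_len(nrow(sidx))) {
      ii <- sidx[i, ] + 1
      if (any(ii < 1) || any(ii > d) || !inwin[ii[1], ii[2], ii[3]])
        stop(sprintf("seed %d at (%.1f, %.1f, %.1f) mm falls outside the HU window",
                     i, seeds[i, 1], seeds[i, 2], seeds[i, 3]))
    }
    # grow: connected component(s) containing the seeds, limited to
    # `iterations` 26-neighbourhood expansion rounds
    lab <- .label_components(inwin, d, 26L)
    seed_labs <- unique(vapply(seq_len(nrow(sidx)), function(i) {
      ii <- sidx[i, ] + 1
      lab[ii[1], ii[2], ii[3]]
    }, integer(1)))
    comp <- array(lab %in% seed_labs, d)
    grown <- array(FALSE, d)
    for (i in seq_len(nrow(sidx))) {
      ii <- sidx[i, ] + 1
      grown[ii[1], ii[2], ii[3]] <- TRUE
    }
    for (r in seq_len(iterations)) {
      nxt <- dilate26(grown) & comp
      if (all(nxt == grown)) { grown <- nxt; break }
      grown <- nxt
    }
    inwin <- grown
  }
  binary_mask(inwin, vol$spacing_mm, vol$origin_mm, vol$direction,
              role = "lumen")
}

dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- out | m[xs, ys, zs]
  }
  out
}

#' Extract calcification near the lumen
#'
#' Voxels strictly above `hu_min` (default 600 HU, distinguishing dense
#' calcification from luminal contrast) are kept when their connected
#' component comes within `proximity_mm` of the lumen mask; components
#' entirely farther away (bone, distant calcification) are discarded. The
#' result is always disjoint from the lumen mask.
#'
#' @param vol an [hu_volume()].
#' @param lumen the lumen [binary_mask()] on the same grid.
#' @param hu_min strict lower HU threshold.
#' @param proximity_mm maximum Euclidean distance (mm) from a component to
#'   the lumen surface.
#' @return a calcification [binary_mask()].
#' @export
extract_calcification <- function(vol, lumen, hu_min = 600,
                                  proximity_mm = 3) {
  stopifnot(inherits(vol, "hu_volume"), inherits(lumen, "binary_mask"))
  if (!same_grid(vol, lumen)) stop("volume and lumen mask grids differ")
  hi <- vol$values > hu_min & !lumen$values
  if (!any(hi)) {
    return(binary_mask(array(FALSE, dim(vol$values)), vol$spacing_mm,
                       vol$origin_mm, vol$direction, role = "calcification"))
  }
  dmap <- distance_to_mask(lumen)$values
  lab <- .label_components(hi, dim(hi), 26L)
  near <- unique(lab[hi & dmap <= proximity_mm])
  near <- near[near > 0]
  keep <- array(lab %in% near & hi, dim(hi))
  binary_mask(keep, vol$spacing_mm, vol$origin_mm, vol$direction,
              role = "calcification")
}
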