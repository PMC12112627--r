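#' Regular 3D Hounsfield-unit volume
#'
#' A minimal grid container for CT-angiography style data: a 3D numeric array
#' of Hounsfield units plus world-coordinate metadata. World coordinates are
#' millimetres on RAS axes (+x right, +y anterior, +z superior); voxel indices
#' are 0-based in world mapping, and `world = origin + direction %*%
#' (index * spacing)`.
#'
#' @param values 3D numeric array (HU).
#' @param spacing_mm numeric(3), positive voxel spacing in mm.
#' @param origin_mm numeric(3), world position of voxel (0,0,0) in mm.
#' @param direction 3x3 orthonormal direction matrix (columns = world
#'   directions of the array axes). Defaults to identity (RAS-aligned).
#' @return An object of class `hu_volume`.
#' @export
hu_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                      direction = diag(3)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) stop("voxel spacing must be positive")
  direction <- as.matrix(direction)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal")
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), direction = direction),
    class = "hu_volume")
}

#' Binary mask on a volume grid
#'
#' Same grid metadata as [hu_volume()] with values in \{0,1\} and a label role
#' recording whether the mask marks the contrast-filled lumen or calcification.
#'
#' @param values 3D array coercible to logical.
#' @param spacing_mm,origin_mm,direction grid metadata, see [hu_volume()].
#' @param role `"lumen"` or `"calcification"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                        direction = diag(3),
                        role = c("lumen", "calcification")) {
  role <- match.arg(role)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  v <- hu_volume(array(as.logical(values), dim(values)), spacing_mm,
                 origin_mm, direction)
  v$role <- role
  class(v) <- c("binary_mask", "hu_volume")
  v
}

#' @export
print.hu_volume <- function(x, ...) {
  kind <- if (inherits(x, "binary_mask")) paste0("binary_mask [", x$role, "]")
          else "hu_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n", kind,
              paste(dim(x$values), collapse = " x "),
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  if (inherits(x, "binary_mask"))
    cat(sprintf("  %d foreground voxels\n", sum(x$values)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

#' Convert between voxel indices and world coordinates
#'
#' @param vol an [hu_volume()] or [binary_mask()].
#' @param idx N x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return N x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind(idx)
  sweep(idx %*% (t(vol$direction) * vol$spacing_mm), 2, vol$origin_mm, "+")
}

#' @rdname voxel_to_world
#' @param xyz N x 3 matrix of world mm coordinates.
#' @return N x 3 matrix of 0-based continuous voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind(xyz)
  rel <- sweep(xyz, 2, vol$origin_mm, "-") %*% vol$direction
  sweep(rel, 2, vol$spacing_mm, "/")
}

#' Sample a volume at world points by trilinear interpolation
#'
#' @param vol an [hu_volume()] or [binary_mask()] (masks are sampled as 0/1).
#' @param xyz N x 3 world mm coordinates.
#' @param fill value returned outside the grid.
#' @return numeric vector of length N.
#' @export
sample_volume <- function(vol, xyz, fill = 0) {
  pts <- world_to_voxel(vol, xyz)
  vals <- as.numeric(vol$values)
  .interp_trilinear(vals, dim(vol$values), pts, fill)
}

#' Euclidean distance map to a mask
#'
#' Exact Euclidean distance (mm) from every voxel centre to the nearest
#' foreground voxel centre of `mask` (0 inside the mask).
#'
#' @param mask a [binary_mask()].
#' @return an [hu_volume()] of distances in mm.
#' @export
distance_to_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- .edt3d(as.logical(mask$values), dim(mask$values), mask$spacing_mm)
  hu_volume(array(d, dim(mask$values)), mask$spacing_mm, mask$origin_mm,
            mask$direction)
}
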