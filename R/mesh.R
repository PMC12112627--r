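#' Triangle mesh in world coordinates
#'
#' @param vertices N x 3 matrix of mm world coordinates.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param role `"lumen"` or `"calcification"`.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, role = c("lumen", "calcification")) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, max(faces) <= nrow(vertices), min(faces) >= 1)
  structure(list(vertices = vertices, faces = faces, role = role),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh [%s]> %d vertices, %d faces, area %.2f mm^2\n",
              x$role, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [tri_mesh()].
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; the absolute value
#' is returned so the result is orientation-independent for consistently
#' oriented closed surfaces.
#' @param mesh a [tri_mesh()].
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6
}

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Surface mesh of a binary mask (voxel-boundary surface)
#'
#' Builds the boundary surface of the voxel set: every voxel face adjacent to
#' background becomes two triangles, placed at the voxel boundary in world
#' coordinates. The surface is watertight and encloses exactly
#' `voxel count x voxel volume`; a single voxel yields a closed cube of one
#' voxel volume. Staircase relief is left to [smooth_lumen_mesh()].
#'
#' @param mask a nonempty [binary_mask()].
#' @return a [tri_mesh()] with the mask's role.
#' @export
mask_to_mesh <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$values
  if (!any(m)) stop("cannot mesh an empty mask")
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  # exposed faces along each axis: voxel TRUE, neighbour FALSE
  idx <- which(pad)
  ai <- arrayInd(idx, dim(pad))
  quads <- list()  # each row: corner index (i,j,k) of voxel, axis, side(0/1)
  shift <- function(da) {
    nb <- cbind(ai[, 1] + da[1], ai[, 2] + da[2], ai[, 3] + da[3])
    exposed <- !pad[nb]
    ai[exposed, , drop = FALSE]
  }
  dirs <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  vkey <- new.env()
  verts <- list()
  faces <- list()
  # corner grid: corner (i,j,k) sits at voxel-boundary index (i-0.5) etc. in
  # the unpadded 0-based index frame; padding offset removed below.
  corner_id <- function(ci) {
    # ci: n x 3 integer corner coordinates (0..d)
    key <- ci[, 1] + (d[1] + 1L) * (ci[, 2] + (d[2] + 1L) * ci[, 3]) + 1L
    key
  }
  all_quads <- list()
  for (q in seq_along(dirs)) {
    da <- dirs[[q]]
    vox <- shift(da)          # padded voxel coords with an exposed face
    if (!nrow(vox)) next
    v0 <- vox - 2L            # 0-based voxel coords in the unpadded grid
    ax <- which(da != 0)
    side <- as.integer(da[ax] > 0)
    # four corners of the exposed face, as 0..d corner-grid coordinates
    base <- v0
    base[, ax] <- base[, ax] + side
    o1 <- c(2, 3, 1)[ax]      # the two in-face axes
    o2 <- c(3, 1, 2)[ax]
    c1 <- base
    c2 <- base; c2[, o1] <- c2[, o1] + 1L
    c3 <- base; c3[, o1] <- c3[, o1] + 1L; c3[, o2] <- c3[, o2] + 1L
    c4 <- base; c4[, o2] <- c4[, o2] + 1L
    if (side == 1L) {
      all_quads[[q]] <- cbind(corner_id(c1), corner_id(c2),
                              corner_id(c3), corner_id(c4))
    } else {
      all_quads[[q]] <- cbind(corner_id(c1), corner_id(c4),
                              corner_id(c3), corner_id(c2))
    }
  }
  quads <- do.call(rbind, all_quads)
  used <- sort(unique(as.vector(quads)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  quads <- matrix(remap[quads], nrow = nrow(quads))
  # corner-grid key back to (i,j,k)
  k0 <- used - 1L
  ci <- k0 %% (d[1] + 1L)
  rest <- k0 %/% (d[1] + 1L)
  cj <- rest %% (d[2] + 1L)
  ck <- rest %/% (d[2] + 1L)
  vox_idx <- cbind(ci - 0.5, cj - 0.5, ck - 0.5)
  verts <- voxel_to_world(mask, vox_idx)
  faces <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  tri_mesh(verts, faces, role = mask$role)
}

mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], e[, 1])
}

#' Smooth a lumen mesh (shrink-compensated Laplacian relaxation)
#'
#' Uniform-weight Laplacian relaxation with the Taubin lambda-mu
#' counter-step: each iteration moves every vertex toward the mean of its
#' one-ring neighbours by `factor`, then applies a slightly larger negative
#' step, which removes voxel staircase without the systematic inward
#' shrinkage of plain Laplacian smoothing (cross-sectional areas of a tube
#' are preserved to well under a percent at the default settings).
#' Calcification surfaces are deliberately never smoothed, so a
#' calcification mesh is refused.
#'
#' @param mesh a lumen [tri_mesh()].
#' @param factor relaxation weight per iteration in `(0, 1]`.
#' @param iterations number of relaxation sweeps.
#' @return the smoothed [tri_mesh()] (same vertex count and faces).
#' @export
smooth_lumen_mesh <- function(mesh, factor = 0.3, iterations = 20L) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (mesh$role != "lumen")
    stop("smoothing is restricted to lumen meshes; calcification stays unsmoothed")
  if (factor == 0 || iterations == 0L) return(mesh)
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  ord <- order(e[, 1])
  e <- e[ord, , drop = FALSE]
  deg <- tabulate(e[, 1], nbins = nrow(mesh$vertices))
  v <- mesh$vertices
  # Taubin counter-step from the passband condition 1/lambda + 1/mu = -k_pb
  mu <- 1 / (-0.1 - 1 / factor)
  relax <- function(v, w) {
    sx <- rowsum(v[e[, 2], 1], e[, 1], reorder = TRUE)
    sy <- rowsum(v[e[, 2], 2], e[, 1], reorder = TRUE)
    sz <- rowsum(v[e[, 2], 3], e[, 1], reorder = TRUE)
    v + w * (cbind(sx, sy, sz) / deg - v)
  }
  for (it in seq_len(iterations)) {
    v <- relax(v, factor)
    v <- relax(v, mu)
  }
  out <- mesh
  out$vertices <- v
  out
}

#' Intersect a mesh with a plane
#'
#' Returns the closed polyline loops of the plane-mesh intersection, in the
#' 2D coordinates of the plane frame `(u, v)` about `origin`.
#'
#' @param mesh a [tri_mesh()].
#' @param origin point on the plane (mm).
#' @param normal unit plane normal.
#' @param u,v unit in-plane axes.
#' @return list of loops; each loop is a closed 2D polygon matrix (first
#'   point not repeated). Empty list when the plane misses the mesh.
#' @export
mesh_plane_loops <- function(mesh, origin, normal, u, v) {
  verts <- mesh$vertices
  sd <- as.numeric(sweep(verts, 2, origin, "-") %*% normal)
  # nudge vertices lying exactly in the plane: keeps the triangle crossing
  # test simple when mesh rings coincide with slicing planes
  sd[abs(sd) < 1e-9] <- 1e-9
  f <- mesh$faces
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) return(list())
  f <- f[crossing, , drop = FALSE]
  segs <- matrix(0, nrow(f), 4)  # (x1,y1,x2,y2) in plane coords
  keep <- logical(nrow(f))
  edge_pt <- function(i1, i2) {
    a <- verts[i1, , drop = FALSE]
    b <- verts[i2, , drop = FALSE]
    t <- sd[i1] / (sd[i1] - sd[i2])
    a + (b - a) * t
  }
  pts2d <- function(p) {
    rel <- sweep(p, 2, origin, "-")
    cbind(rel %*% u, rel %*% v)
  }
  out <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    ii <- f[i, ]
    ss <- sd[ii]
    pos <- ii[ss > 0]; neg <- ii[ss <= 0]
    if (length(pos) == 0 || length(neg) == 0) next
    if (length(pos) == 1) {
      p1 <- edge_pt(pos[1], neg[1]); p2 <- edge_pt(pos[1], neg[2])
    } else {
      p1 <- edge_pt(pos[1], neg[1]); p2 <- edge_pt(pos[2], neg[1])
    }
    q <- pts2d(rbind(p1, p2))
    segs[i, ] <- c(q[1, ], q[2, ])
    keep[i] <- TRUE
  }
  segs <- segs[keep, , drop = FALSE]
  chain_segments(segs)
}

# Chain unordered 2D segments into closed loops by endpoint matching.
chain_segments <- function(segs, tol = 1e-6) {
  n <- nrow(segs)
  if (n == 0) return(list())
  ends <- rbind(segs[, 1:2], segs[, 3:4])
  # snap endpoints onto a grid to make matching robust
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
  ids <- match(key, unique(key))
  e1 <- ids[seq_len(n)]
  e2 <- ids[n + seq_len(n)]
  used <- logical(n)
  # adjacency: for each snapped point, which segments touch it
  touch <- split(rep(seq_len(n), 2), c(e1, e2))
  loops <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    loop_pts <- list(segs[start, 1:2])
    used[start] <- TRUE
    cur_pt <- e2[start]
    loop_pts[[2]] <- segs[start, 3:4]
    first_pt <- e1[start]
    repeat {
      cand <- touch[[as.character(cur_pt)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      nxt <- cand[1]
      used[nxt] <- TRUE
      if (e1[nxt] == cur_pt) {
        loop_pts[[length(loop_pts) + 1L]] <- segs[nxt, 3:4]
        cur_pt <- e2[nxt]
      } else {
        loop_pts[[length(loop_pts) + 1L]] <- segs[nxt, 1:2]
        cur_pt <- e1[nxt]
      }
      if (cur_pt == first_pt) break
    }
    if (length(loop_pts) >= 4 && cur_pt == first_pt) {
      m <- do.call(rbind, loop_pts[-length(loop_pts)])
      loops[[length(loops) + 1L]] <- m
    }
  }
  loops
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

point_in_polygon <- function(pt, poly) {
  # even-odd ray casting
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((y[i] > pt[2]) != (y[j[i]] > pt[2])) &&
        (pt[1] < (x[j[i]] - x[i]) * (pt[2] - y[i]) / (y[j[i]] - y[i]) + x[i]))
      inside <- !inside
  }
  inside
}
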