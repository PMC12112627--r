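#' Read and write volumes (NIfTI, NRRD)
#'
#' World-coordinate metadata (spacing, origin, direction) is preserved
#' exactly on a write/read round trip. NIfTI files go through the RNifti
#' sform; NRRD files use the text-header format with raw little-endian
#' encoding.
#'
#' @param path file path; format inferred from the extension
#'   (`.nii`, `.nii.gz` or `.nrrd`) unless given.
#' @param format `"nifti"`, `"nrrd"` or `"auto"`.
#' @return [read_volume()]: an [hu_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    vals <- array(as.numeric(img), dim(img))
    spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
    direction <- sweep(aff[1:3, 1:3], 2, spacing, "/")
    if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
      stop("non-orthonormal direction matrix in NIfTI header")
    hu_volume(vals, spacing, aff[1:3, 4], direction)
  } else {
    read_nrrd(path)
  }
}

#' @rdname read_volume
#' @param vol an [hu_volume()] or [binary_mask()] (masks are written as 0/1).
#' @export
write_volume <- function(vol, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  vals <- vol$values
  if (is.logical(vals)) vals <- array(as.numeric(vals), dim(vals))
  if (format == "nifti") {
    img <- RNifti::asNifti(vals)
    aff <- rbind(cbind(sweep(vol$direction, 2, vol$spacing_mm, "*"),
                       vol$origin_mm), c(0, 0, 0, 1))
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(vol, path)
  }
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
  else stop("cannot infer volume format from extension: ", path)
}

write_nrrd <- function(vol, path) {
  dirs <- sweep(vol$direction, 2, vol$spacing_mm, "*")
  vecfmt <- function(x) sprintf("(%.17g,%.17g,%.17g)", x[1], x[2], x[3])
  header <- c(
    "NRRD0004",
    "# written by calcimorph",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(vol$values)[1], dim(vol$values)[2],
            dim(vol$values)[3]),
    "space: right-anterior-superior",
    sprintf("space directions: %s %s %s", vecfmt(dirs[, 1]),
            vecfmt(dirs[, 2]), vecfmt(dirs[, 3])),
    sprintf("space origin: %s", vecfmt(vol$origin_mm)),
    "encoding: raw",
    "endian: little",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  vals <- vol$values
  if (is.logical(vals)) vals <- as.numeric(vals)
  writeBin(as.numeric(vals), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line) || line == "") break
    header <- c(header, line)
  }
  get_field <- function(name) {
    ln <- grep(paste0("^", name, ": ?"), header, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", name, ": ?"), "", ln[1])
  }
  if (!grepl("^NRRD", header[1])) stop("malformed NRRD header: ", path)
  type <- get_field("type")
  enc <- get_field("encoding")
  if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported")
  parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  sd_raw <- get_field("space directions")
  dirs <- if (is.null(sd_raw)) diag(3) else {
    parts <- regmatches(sd_raw, gregexpr("\\([^)]*\\)", sd_raw))[[1]]
    do.call(cbind, lapply(parts, parse_vec))
  }
  origin <- get_field("space origin")
  origin <- if (is.null(origin)) c(0, 0, 0) else parse_vec(origin)
  spacing <- sqrt(colSums(dirs^2))
  direction <- sweep(dirs, 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("non-orthonormal direction matrix in NRRD header")
  n <- prod(sizes)
  vals <- switch(type,
    "double" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "float" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "short" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "int" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "uchar" = as.numeric(readBin(con, "integer", n = n, size = 1,
                                 signed = FALSE)),
    stop("unsupported NRRD type: ", type))
  hu_volume(array(as.numeric(vals), sizes), spacing, origin, direction)
}

#' Read and write triangle meshes (ASCII STL, ASCII PLY)
#'
#' @param path file path (`.stl` or `.ply`).
#' @param role mesh role recorded on read.
#' @return [read_mesh()]: a [tri_mesh()].
#' @export
read_mesh <- function(path, role = c("lumen", "calcification")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.stl$", path, ignore.case = TRUE)) read_stl(path, role)
  else if (grepl("\\.ply$", path, ignore.case = TRUE)) read_ply(path, role)
  else stop("unsupported mesh format: ", path)
}

#' @rdname read_mesh
#' @param mesh a [tri_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  if (grepl("\\.stl$", path, ignore.case = TRUE)) write_stl(mesh, path)
  else if (grepl("\\.ply$", path, ignore.case = TRUE)) write_ply(mesh, path)
  else stop("unsupported mesh format: ", path)
  invisible(path)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$role), con)
  block <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3],
    p3[, 1], p3[, 2], p3[, 3])
  writeLines(block, con)
  writeLines(sprintf("endsolid %s", mesh$role), con)
}

read_stl <- function(path, role) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (nrow(nums) %% 3 != 0) stop("malformed STL: ", path)
  # deduplicate vertices
  key <- apply(round(nums, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces, role)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

read_ply <- function(path, role) {
  lines <- readLines(path, warn = FALSE)
  endh <- which(lines == "end_header")[1]
  if (is.na(endh)) stop("malformed PLY: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vlines <- lines[endh + seq_len(nv)]
  flines <- lines[endh + nv + seq_len(nf)]
  verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x)
    as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x)
    as.integer(x[2:4]) + 1L))
  tri_mesh(verts, faces, role)
}
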