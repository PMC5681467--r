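## Presentation: colorized 2D overlays (PNG) and 3D surface meshes (binary
## STL). The mesh is the 0.5 iso-surface of a binary mask extracted as
## voxel-face quads (cuberille), triangulated with outward orientation;
## coordinates are physical (micrometres). Smoothing is left to downstream
## tools.

#' Colorized mask overlay for one slice
#'
#' Renders the grayscale slice to RGB and alpha-blends each mask with its
#' color. Pixels in no mask keep their grayscale value; where masks
#' overlap, the last-listed mask wins.
#'
#' @param slice 2D matrix (y, x).
#' @param masks list of binary 2D matrices, same geometry.
#' @param colors character vector of distinct colors, one per mask.
#' @param alpha blend weight in \[0, 1\] (1 = opaque color).
#' @param range optional `c(lo, hi)` grayscale display range (defaults to
#'   the slice min-max).
#' @return `ny x nx x 3` RGB array with values in \[0, 1\].
#' @export
overlay_masks <- function(slice, masks, colors, alpha = 0.5, range = NULL) {
  slice <- as_slice(slice)
  if (length(masks) != length(colors))
    stop("need one color per mask")
  if (anyDuplicated(colors)) stop("mask colors must be distinct")
  for (m in masks)
    if (!identical(dim(m), dim(slice))) stop("mask geometry mismatch")
  if (is.null(range)) range <- c(min(slice), max(slice))
  g <- if (range[2] > range[1])
    pmin(pmax((slice - range[1]) / (range[2] - range[1]), 0), 1)
  else slice * 0
  rgb <- array(rep(g, 3), c(dim(slice), 3L))
  for (i in seq_along(masks)) {
    cc <- grDevices::col2rgb(colors[i])[, 1] / 255
    sel <- masks[[i]] == 1
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * cc[ch]
      rgb[, , ch] <- plane
    }
  }
  rgb
}

#' Write an overlay as PNG
#' @param rgb array from [overlay_masks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

## quad corner templates per face direction, in (x, y, z) offsets from the
## voxel's low corner; winding is counter-clockwise seen from outside
.face_corners <- list(
  xp = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)),
  xm = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)),
  yp = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0)),
  ym = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
  zp = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
  zm = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
## neighbour offset (dz, dy, dx) whose emptiness exposes each face
.face_dir <- list(xp = c(0, 0, 1), xm = c(0, 0, -1), yp = c(0, 1, 0),
                  ym = c(0, -1, 0), zp = c(1, 0, 0), zm = c(-1, 0, 0))

#' Surface mesh of a binary mask
#'
#' Extracts the boundary between foreground and background voxels as a
#' triangulated, outward-oriented surface with vertices in micrometres.
#' The volume is padded with one background layer first, so masks touching
#' the volume boundary still yield closed (watertight) surfaces; for a
#' solid shape the enclosed mesh volume equals the voxel count times the
#' voxel volume exactly.
#'
#' @param mask non-empty binary 3D array.
#' @param voxel_size_um isotropic voxel edge in micrometres.
#' @param provenance free-text note on which mask produced the mesh.
#' @return A `mesh_model`: `vertices` (n x 3, columns x/y/z in um),
#'   `faces` (m x 3 vertex indices), `provenance`.
#' @export
mask_to_mesh <- function(mask, voxel_size_um = 8, provenance = "mask") {
  mask <- as_mask(mask)
  if (sum(mask) == 0) stop("cannot mesh an empty mask")
  fg <- mask == 1L
  tris <- list()   # one row per triangle: 9 columns (x,y,z of 3 corners)
  for (f in names(.face_dir)) {
    dd <- .face_dir[[f]]
    nb <- shift3(fg, -dd[1], -dd[2], -dd[3], pad = FALSE)
    idx <- which(fg & !nb, arr.ind = TRUE)   # exposed faces
    if (nrow(idx) == 0L) next
    ## voxel low corner in (x, y, z) voxel units, 0-based
    low <- cbind(idx[, 3] - 1L, idx[, 2] - 1L, idx[, 1] - 1L)
    tpl <- .face_corners[[f]]
    quad <- lapply(1:4, function(c4) sweep(low, 2, tpl[c4, ], "+"))
    ## two triangles per quad, same winding
    tris[[f]] <- rbind(cbind(quad[[1]], quad[[2]], quad[[3]]),
                       cbind(quad[[1]], quad[[3]], quad[[4]]))
  }
  tris <- do.call(rbind, tris)
  ## deduplicate vertices
  allv <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  key <- paste(allv[, 1], allv[, 2], allv[, 3])
  uk <- !duplicated(key)
  verts <- allv[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  m <- nrow(tris)
  faces <- cbind(idx[seq_len(m)], idx[m + seq_len(m)], idx[2 * m + seq_len(m)])
  structure(list(vertices = verts * voxel_size_um, faces = faces,
                 provenance = provenance),
            class = "mesh_model")
}

#' @export
print.mesh_model <- function(x, ...) {
  cat(sprintf("<mesh_model> %d vertices, %d triangles (%s)\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  invisible(x)
}

#' Euler characteristic of a mesh
#'
#' `V - E + F` over unique vertices and undirected edges: 2 for a closed
#' sphere-topology surface, 0 for a torus (e.g. an open-ended tube wall),
#' lower for higher genus.
#'
#' @param mesh a `mesh_model`.
#' @return integer Euler characteristic.
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ne <- nrow(unique(e))
  nrow(mesh$vertices) - ne + nrow(f)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of tetrahedra against the
#' origin); positive for outward-oriented closed surfaces. Units are the
#' cube of the vertex units (um^3).
#'
#' @param mesh a `mesh_model`.
#' @return scalar volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Write a mesh as binary STL
#'
#' Standard little-endian binary stereolithography layout: 80-byte header,
#' uint32 triangle count, then per triangle a float32 normal, three float32
#' vertices and a uint16 attribute. Round-trips through [read_stl()] up to
#' float32 quantization.
#'
#' @param mesh a non-empty `mesh_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L)
    stop("refusing to write an empty mesh")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "tubuseg binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  payload <- t(cbind(n, a, b, c3))          # 12 floats per triangle
  attr16 <- writeBin(0L, raw(), size = 2, endian = "little")
  for (t in seq_len(nrow(f))) {
    writeBin(as.numeric(payload[, t]), con, size = 4, endian = "little")
    writeBin(attr16, con)
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' @param path STL file path.
#' @return list with `triangles` (m x 9 matrix, vertex coordinates per
#'   row), `normals` (m x 3), `n_triangles`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), n = 80)
  m <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  tri <- matrix(0, m, 9); nrm <- matrix(0, m, 3)
  for (t in seq_len(m)) {
    vals <- readBin(con, numeric(), n = 12, size = 4, endian = "little")
    readBin(con, raw(), n = 2)
    nrm[t, ] <- vals[1:3]
    tri[t, ] <- vals[4:12]
  }
  list(triangles = tri, normals = nrm, n_triangles = m)
}
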