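## Out-of-core block store: a large volume is processed as a grid of cubic
## sub-volumes, each persisted as a loss-less TIFF, with one JSON sidecar of
## global properties (dims, intensity range, histogram) so that per-block
## processing stays consistent with the whole volume.

#' Plan a block grid for a volume
#'
#' Partitions a `(nz, ny, nx)` volume into cubic blocks of edge
#' `block_edge`; blocks at the far faces may be smaller, so every voxel
#' belongs to exactly one core block. The per-axis block count is the
#' ceiling division `ceil(dim / block_edge)`. Blocks enumerate in row-major
#' order with the x grid index fastest.
#'
#' @param dims integer vector `(nz, ny, nx)`, all >= 1.
#' @param block_edge cubic block edge in voxels (default 256, which together
#'   with halo 16 matches typical lung micro-CT processing runs).
#' @param halo halo width in voxels borrowed from neighbouring blocks when a
#'   block is read for footprint-limited filtering; `0` disables halos.
#' @return A `block_grid` with `counts` per axis and `n_blocks`.
#' @examples
#' g <- plan_grid(c(1200, 1600, 1600), block_edge = 256)
#' g$n_blocks  # 245
#' @export
plan_grid <- function(dims, block_edge = 256L, halo = 0L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be three positive voxel counts (nz, ny, nx)")
  block_edge <- as.integer(block_edge)
  if (length(block_edge) != 1L || is.na(block_edge) || block_edge < 1L)
    stop("`block_edge` must be a positive integer")
  halo <- as.integer(halo)
  if (length(halo) != 1L || is.na(halo) || halo < 0L)
    stop("`halo` must be a non-negative integer")
  counts <- as.integer(ceiling(dims / block_edge))
  structure(list(dims = dims, block_edge = block_edge, halo = halo,
                 counts = counts, n_blocks = as.integer(prod(counts))),
            class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("<block_grid> %s voxels, edge %d, halo %d -> %s blocks = %d\n",
              paste(x$dims, collapse = "x"), x$block_edge, x$halo,
              paste(x$counts, collapse = "x"), x$n_blocks))
  invisible(x)
}

## all (i,j,k) grid indices in enumeration order (k fastest), 0-based
block_indices <- function(grid) {
  idx <- expand.grid(k = seq_len(grid$counts[3]) - 1L,
                     j = seq_len(grid$counts[2]) - 1L,
                     i = seq_len(grid$counts[1]) - 1L)
  as.matrix(idx[, c("i", "j", "k")])
}

#' Core and halo extent of one block
#'
#' Voxel ranges are half-open `[lo, hi)` in 0-based volume coordinates.
#' `halo_extent` is the core expanded by `grid$halo` per side, before any
#' clipping to the volume.
#'
#' @param grid a [plan_grid()] result.
#' @param index 0-based grid index `(i, j, k)` along `(z, y, x)`.
#' @return list with `index`, `core` (3x2 matrix), `halo_extent`.
#' @export
block_ref <- function(grid, index) {
  index <- as.integer(index)
  if (any(index < 0L) || any(index >= grid$counts))
    stop("block index (", paste(index, collapse = ","), ") outside grid")
  lo <- index * grid$block_edge
  hi <- pmin(lo + grid$block_edge, grid$dims)
  core <- cbind(lo = lo, hi = hi)
  rownames(core) <- c("z", "y", "x")
  halo_extent <- cbind(lo = lo - grid$halo, hi = hi + grid$halo)
  rownames(halo_extent) <- c("z", "y", "x")
  list(index = index, core = core, halo_extent = halo_extent)
}

block_filename <- function(index)
  sprintf("block_%04d_%04d_%04d.tif", index[1], index[2], index[3])

hist_counts <- function(x, gmin, gmax, bins = 256L) {
  if (gmax <= gmin) {
    counts <- integer(bins); counts[1] <- length(x)
    return(counts)
  }
  idx <- pmin(floor((as.numeric(x) - gmin) / (gmax - gmin) * bins) + 1, bins)
  tabulate(idx, nbins = bins)
}

meta_path <- function(path) file.path(path, "meta.json")

write_meta <- function(path, meta) {
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

read_meta <- function(path) {
  m <- jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
  m$dims <- as.integer(m$dims)
  m$counts <- as.integer(m$counts)
  m
}

#' Split a volume into a block store on disk
#'
#' Writes one uncompressed TIFF per core block (halos are constructed on
#' read, not stored) plus a `meta.json` sidecar holding the global
#' properties of the image: dims, voxel size, bit depth, grid parameters,
#' global min/max, and a 256-bin intensity histogram. The sidecar is what
#' keeps intensity handling consistent when blocks are processed
#' independently. No voxel value is altered.
#'
#' @param volume a [ct_volume()] (or bare 3D array).
#' @param store_path directory to create.
#' @param block_edge,halo grid parameters, see [plan_grid()].
#' @param overwrite refuse an existing non-empty store unless `TRUE`.
#' @param bins histogram bin count for the sidecar.
#' @return A `block_store` handle (path + metadata).
#' @export
split_volume <- function(volume, store_path, block_edge = 256L, halo = 16L,
                         overwrite = FALSE, bins = 256L) {
  volume <- as_volume(volume)
  grid <- plan_grid(dim(volume$data), block_edge, halo)
  if (file.exists(meta_path(store_path)) && !overwrite)
    stop("store already exists at ", store_path,
         " (use overwrite = TRUE to replace)")
  dir.create(store_path, showWarnings = FALSE, recursive = TRUE)
  gmin <- min(volume$data); gmax <- max(volume$data)
  enc <- encoding_for(volume$dtype_bits, gmin, gmax)
  counts <- hist_counts(volume$data, gmin, gmax, bins)
  edges <- if (gmax > gmin) seq(gmin, gmax, length.out = bins + 1)
           else c(gmin, gmin + seq_len(bins) * 0)
  meta <- list(dims = grid$dims, voxel_size_um = volume$voxel_size_um,
               dtype_bits = volume$dtype_bits,
               block_edge = grid$block_edge, halo = grid$halo,
               counts = grid$counts, block_count = grid$n_blocks,
               global_min = gmin, global_max = gmax,
               histogram = list(edges = edges, counts = counts),
               encoding = enc)
  idx <- block_indices(grid)
  bits <- if (enc$mode == "uint") enc$bits else 32L
  for (r in seq_len(nrow(idx))) {
    ref <- block_ref(grid, idx[r, ])
    co <- ref$core
    blk <- volume$data[(co["z", 1] + 1):co["z", 2],
                       (co["y", 1] + 1):co["y", 2],
                       (co["x", 1] + 1):co["x", 2], drop = FALSE]
    write_tiff_zyx(blk, file.path(store_path, block_filename(idx[r, ])),
                   enc, bits)
  }
  write_meta(store_path, meta)
  load_block_store(store_path)
}

#' Open an existing block store
#' @param path store directory containing `meta.json`.
#' @return A `block_store` handle.
#' @export
load_block_store <- function(path) {
  if (!file.exists(meta_path(path)))
    stop("no block store at ", path, " (missing meta.json)")
  structure(list(path = path, meta = read_meta(path)), class = "block_store")
}

#' @export
print.block_store <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<block_store> %s: %s voxels, %d blocks (edge %d, halo %d)\n",
              x$path, paste(m$dims, collapse = "x"), m$block_count,
              m$block_edge, m$halo))
  invisible(x)
}

store_grid <- function(store)
  plan_grid(store$meta$dims, store$meta$block_edge, store$meta$halo)

#' Read one core block from a store
#' @param store a `block_store`.
#' @param index 0-based grid index `(i, j, k)`.
#' @return 3D array of the block's core voxels.
#' @export
read_block <- function(store, index) {
  grid <- store_grid(store)
  ref <- block_ref(grid, index)  # validates index
  f <- file.path(store$path, block_filename(ref$index))
  if (!file.exists(f))
    stop("incomplete store: missing block (",
         paste(ref$index, collapse = ","), ")")
  read_tiff_zyx(f, store$meta$encoding)
}

#' Reassemble a volume from a block store
#'
#' Exact inverse of [split_volume()]: concatenates all core blocks back into
#' a single volume. Every grid index must be present.
#'
#' @param store a `block_store`.
#' @return A [ct_volume()] with the store's recorded geometry.
#' @export
assemble_volume <- function(store) {
  grid <- store_grid(store)
  arr <- array(0, grid$dims)
  idx <- block_indices(grid)
  for (r in seq_len(nrow(idx))) {
    ref <- block_ref(grid, idx[r, ])
    co <- ref$core
    arr[(co["z", 1] + 1):co["z", 2],
        (co["y", 1] + 1):co["y", 2],
        (co["x", 1] + 1):co["x", 2]] <- read_block(store, idx[r, ])
  }
  ct_volume(arr, voxel_size_um = store$meta$voxel_size_um,
            dtype_bits = store$meta$dtype_bits)
}

#' Read a block padded with a halo
#'
#' Halo voxels are taken from neighbouring blocks (halo exchange); at the
#' volume boundary the missing planes are filled by mirror reflection, so
#' footprint-limited filters behave at block seams exactly as they would on
#' the unsplit volume.
#'
#' @param store a `block_store`.
#' @param index 0-based grid index.
#' @param halo halo width; must not exceed the block edge. Defaults to the
#'   store's planned halo.
#' @return 3D array of shape core + 2*halo per axis.
#' @export
read_block_with_halo <- function(store, index, halo = NULL) {
  m <- store$meta
  if (is.null(halo)) halo <- m$halo
  halo <- as.integer(halo)
  if (halo < 0L || halo > m$block_edge)
    stop("`halo` must be in [0, block_edge]")
  grid <- store_grid(store)
  ref <- block_ref(grid, index)
  if (halo == 0L) return(read_block(store, index))
  co <- ref$core
  n <- grid$dims
  win <- read_block_clipped(store, index, halo)
  ext_lo <- unname(pmax(co[, 1] - halo, 0L))
  ## map padded global coordinates through mirror reflection into the extent
  map_axis <- function(a) {
    g <- (co[a, 1] - halo):(co[a, 2] + halo - 1L)
    g <- vapply(g, reflect_r, 0L, n = n[a])
    g - ext_lo[a] + 1L
  }
  win$data[map_axis(1), map_axis(2), map_axis(3), drop = FALSE]
}

## read a block plus halo, clipped at the volume boundary (no mirror fill):
## each voxel of the window is real data, and a filter applied to it sees
## the true volume edge wherever the window is clipped. This is what makes
## blockwise processing equal whole-volume processing even for cascaded
## filters whose boundary handling is not mirror-symmetric.
read_block_clipped <- function(store, index, halo) {
  m <- store$meta
  halo <- as.integer(halo)
  grid <- store_grid(store)
  ref <- block_ref(grid, index)
  co <- ref$core
  n <- grid$dims
  ext_lo <- unname(pmax(co[, 1] - halo, 0L))
  ext_hi <- unname(pmin(co[, 2] + halo, n))
  gather <- array(0, ext_hi - ext_lo)
  blo <- ext_lo %/% m$block_edge
  bhi <- (ext_hi - 1L) %/% m$block_edge
  for (bi in blo[1]:bhi[1]) for (bj in blo[2]:bhi[2]) for (bk in blo[3]:bhi[3]) {
    nref <- block_ref(grid, c(bi, bj, bk))
    nc <- nref$core
    ilo <- pmax(nc[, 1], ext_lo); ihi <- pmin(nc[, 2], ext_hi)
    blk <- read_block(store, c(bi, bj, bk))
    gather[(ilo[1] - ext_lo[1] + 1):(ihi[1] - ext_lo[1]),
           (ilo[2] - ext_lo[2] + 1):(ihi[2] - ext_lo[2]),
           (ilo[3] - ext_lo[3] + 1):(ihi[3] - ext_lo[3])] <-
      blk[(ilo[1] - nc[1, 1] + 1):(ihi[1] - nc[1, 1]),
          (ilo[2] - nc[2, 1] + 1):(ihi[2] - nc[2, 1]),
          (ilo[3] - nc[3, 1] + 1):(ihi[3] - nc[3, 1]), drop = FALSE]
  }
  list(data = gather, pre = unname(co[, 1] - ext_lo),
       core_dim = unname(co[, 2] - co[, 1]))
}

## reflect-with-edge-duplication, 0-based (matches the C++ convolution)
reflect_r <- function(p, n) {
  if (n == 1L) return(0L)
  while (p < 0L || p >= n) {
    if (p < 0L) p <- -1L - p
    if (p >= n) p <- 2L * n - 1L - p
  }
  as.integer(p)
}

#' Apply a voxel operator block-by-block
#'
#' Reads each block in a window extended by `halo` voxels of neighbouring
#' data, applies `voxel_op`, crops the halo and writes the result to a new
#' store. Windows are clipped at the volume boundary (not mirror-filled),
#' so the operator's own boundary handling acts at the true volume edge;
#' for any operator whose spatial footprint radius is at most `halo`, the
#' assembled result therefore equals applying the operator to the unsplit
#' volume, and blocks may be processed in any order.
#'
#' @param store input `block_store`.
#' @param voxel_op function taking and returning a 3D array of unchanged
#'   shape (e.g. a smoothing filter).
#' @param out_path output store directory.
#' @param halo halo width in voxels; must be at least the operator's
#'   footprint radius for seam-free results.
#' @param out_bits bit depth of the output store (default: same as input;
#'   use 32 for float-valued operators).
#' @param overwrite refuse an existing store unless `TRUE`.
#' @param indices optional matrix of grid indices giving the processing
#'   order (default: enumeration order); the result is order-independent.
#' @return A `block_store` handle for the output.
#' @export
map_blocks <- function(store, voxel_op, out_path, halo = NULL,
                       out_bits = NULL, overwrite = FALSE, indices = NULL) {
  m <- store$meta
  if (is.null(halo)) halo <- m$halo
  if (is.null(out_bits)) out_bits <- m$dtype_bits
  out_bits <- as.integer(out_bits)
  if (file.exists(meta_path(out_path)) && !overwrite)
    stop("store already exists at ", out_path,
         " (use overwrite = TRUE to replace)")
  dir.create(out_path, showWarnings = FALSE, recursive = TRUE)
  grid <- store_grid(store)
  if (is.null(indices)) indices <- block_indices(grid)
  gmin <- Inf; gmax <- -Inf
  ## stage processed blocks loss-lessly, then encode once the range is known
  for (r in seq_len(nrow(indices))) {
    win <- read_block_clipped(store, indices[r, ], halo)
    res <- voxel_op(win$data)
    if (!identical(dim(res), dim(win$data)))
      stop("contract violation: voxel_op changed block shape for block (",
           paste(indices[r, ], collapse = ","), ")")
    res <- res[win$pre[1] + seq_len(win$core_dim[1]),
               win$pre[2] + seq_len(win$core_dim[2]),
               win$pre[3] + seq_len(win$core_dim[3]), drop = FALSE]
    gmin <- min(gmin, res); gmax <- max(gmax, res)
    saveRDS(res, file.path(out_path,
                           sub("\\.tif$", ".rds", block_filename(indices[r, ]))))
  }
  enc <- encoding_for(out_bits, gmin, gmax)
  bits <- if (enc$mode == "uint") enc$bits else 32L
  idx <- block_indices(grid)
  hedges <- if (gmax > gmin) seq(gmin, gmax, length.out = 257)
            else c(gmin, gmin + numeric(256))
  hcounts <- integer(256)
  for (r in seq_len(nrow(idx))) {
    stage <- file.path(out_path, sub("\\.tif$", ".rds", block_filename(idx[r, ])))
    res <- readRDS(stage)
    hcounts <- hcounts + hist_counts(res, gmin, gmax, 256L)
    write_tiff_zyx(res, file.path(out_path, block_filename(idx[r, ])),
                   enc, bits)
    unlink(stage)
  }
  meta <- list(dims = grid$dims, voxel_size_um = m$voxel_size_um,
               dtype_bits = out_bits,
               block_edge = m$block_edge, halo = m$halo,
               counts = grid$counts, block_count = grid$n_blocks,
               global_min = gmin, global_max = gmax,
               histogram = list(edges = hedges, counts = hcounts),
               encoding = enc)
  write_meta(out_path, meta)
  load_block_store(out_path)
}

#' Recompute global metadata from the blocks
#'
#' Aggregates min, max and the intensity histogram over all blocks; the
#' result equals the same statistics computed on the unsplit volume and is
#' written back to the `meta.json` sidecar.
#'
#' @param store a complete `block_store`.
#' @param bins histogram bin count (default 256); bin edges span
#'   `[global_min, global_max]` and are recorded explicitly.
#' @return The updated metadata list, invisibly a `block_store`.
#' @export
compute_meta <- function(store, bins = 256L) {
  grid <- store_grid(store)
  idx <- block_indices(grid)
  gmin <- Inf; gmax <- -Inf
  bits_seen <- NULL
  for (r in seq_len(nrow(idx))) {
    blk <- read_block(store, idx[r, ])
    gmin <- min(gmin, blk); gmax <- max(gmax, blk)
  }
  counts <- integer(bins)
  nvox <- 0
  for (r in seq_len(nrow(idx))) {
    blk <- read_block(store, idx[r, ])
    counts <- counts + hist_counts(blk, gmin, gmax, bins)
    nvox <- nvox + length(blk)
  }
  stopifnot(nvox == prod(grid$dims))
  edges <- if (gmax > gmin) seq(gmin, gmax, length.out = bins + 1)
           else c(gmin, gmin + numeric(bins))
  meta <- store$meta
  meta$global_min <- gmin; meta$global_max <- gmax
  meta$histogram <- list(edges = edges, counts = counts)
  write_meta(store$path, meta)
  store$meta <- meta
  store
}
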