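#' 3D intensity volume
#'
#' In-memory container for a 3D grayscale scan. The data array is indexed
#' `(z, y, x)` with 0-based voxel coordinates in all user-facing coordinate
#' arguments; `dims` is `(nz, ny, nx)`. Micro-CT reconstructions of
#' wax-embedded tissue are typically isotropic (e.g. 8 um voxels) and 8, 16
#' or 32 bits per voxel; all derived maps (probabilities, masks) share the
#' volume's geometry.
#'
#' @param data 3D numeric array with `dim = c(nz, ny, nx)`.
#' @param voxel_size_um positive scalar, isotropic voxel edge in micrometres.
#' @param dtype_bits storage depth, one of 8, 16, 32 (8/16 are unsigned
#'   integer ranges; 32 is floating point).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, voxel_size_um = 8, dtype_bits = 32L) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all dims must be >= 1")
  if (!all(is.finite(data))) stop("intensity values must be finite")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  dtype_bits <- as.integer(dtype_bits)
  if (!dtype_bits %in% c(8L, 16L, 32L))
    stop("`dtype_bits` must be one of 8, 16, 32")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 dtype_bits = dtype_bits),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (z,y,x), %g um/voxel, %d-bit\n",
              d[1], d[2], d[3], x$voxel_size_um, x$dtype_bits))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

as_volume <- function(x, voxel_size_um = 8, dtype_bits = 32L) {
  if (inherits(x, "ct_volume")) x
  else ct_volume(x, voxel_size_um = voxel_size_um, dtype_bits = dtype_bits)
}

## ---- TIFF slice-stack I/O -------------------------------------------------

## tiff::writeTIFF persists sample values in [0, 1] only, truncating to the
## target integer depth. Integer volumes (8/16-bit) scale by 1/(2^bits - 1),
## which round-trips bit-exactly. 32-bit volumes are stored as uint32 on a
## power-of-two grid of step 2^(k-32) over [0, 2^k] (k recorded in the store
## sidecar), which is bit-exact for integer-valued data and quantizes other
## values to the grid; data with negative values fall back to an affine
## [min, max] -> [0, 1] map at uint32 precision.
encoding_for <- function(dtype_bits, gmin, gmax) {
  dtype_bits <- as.integer(dtype_bits)
  if (dtype_bits %in% c(8L, 16L))
    return(list(mode = "uint", bits = dtype_bits))
  if (gmin >= 0) {
    k <- if (gmax <= 1) 0L else as.integer(ceiling(log2(gmax)))
    list(mode = "pow2", bits = 32L, k = k)
  } else if (gmax > gmin) {
    list(mode = "affine", bits = 32L, offset = gmin, scale = gmax - gmin)
  } else {
    list(mode = "affine", bits = 32L, offset = gmin, scale = 1)
  }
}

## encode to the [0,1] sample values writeTIFF expects; the +0.5 half-step
## offset makes the library's truncation land on the intended integer code
encode_intensity <- function(x, enc) {
  switch(enc$mode,
    uint = pmin(pmax(round(x), 0), 2^enc$bits - 1) / (2^enc$bits - 1),
    pow2 = {
      q <- pmin(pmax(round(x * 2^(32 - enc$k)), 0), 2^32 - 1)
      pmin((q + 0.5) / (2^32 - 1), 1)
    },
    affine = {
      v <- pmin(pmax((x - enc$offset) / enc$scale, 0), 1)
      q <- round(v * (2^32 - 1))
      pmin((q + 0.5) / (2^32 - 1), 1)
    },
    stop("unknown intensity encoding"))
}

## decode the integer codes returned by readTIFF(as.is = TRUE); 32-bit codes
## arrive as signed int32 bit patterns (0x80000000 surfaces as NA)
decode_codes <- function(u, enc) {
  u <- as.numeric(u)
  if (enc$bits == 32L) {
    u[is.na(u)] <- -2^31
    u[u < 0] <- u[u < 0] + 2^32
  }
  switch(enc$mode,
    uint = u,
    pow2 = u * 2^(enc$k - 32),
    affine = u / (2^32 - 1) * enc$scale + enc$offset,
    stop("unknown intensity encoding"))
}

## write a (z,y,x) array as a multi-page TIFF, one page per z slice
write_tiff_zyx <- function(arr, path, enc, bits = enc$bits) {
  pages <- lapply(seq_len(dim(arr)[1]), function(z) {
    m <- encode_intensity(arr[z, , , drop = TRUE], enc)
    if (is.null(dim(m))) m <- matrix(m, dim(arr)[2], dim(arr)[3])
    m
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                                   compression = "none"))
  invisible(path)
}

read_tiff_zyx <- function(path, enc) {
  raw01 <- identical(enc$mode, "raw01")   # external float TIFF, values [0,1]
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !raw01)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  arr <- array(0, c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_len(nz))
    arr[z, , ] <- if (raw01) pages[[z]] else decode_codes(pages[[z]], enc)
  arr
}

#' Read a volume from TIFF
#'
#' Accepts a multi-page TIFF or a directory of single-slice TIFF files;
#' slices in a directory are stacked in lexicographic filename order, which
#' is taken as increasing z.
#'
#' @param path file or directory path.
#' @param voxel_size_um voxel size to record (TIFF rarely carries it).
#' @param dtype_bits storage depth; defaults to the file's bits-per-sample.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, voxel_size_um = 8, dtype_bits = NULL) {
  paths <- if (dir.exists(path)) {
    fs <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(fs) == 0L) stop("no TIFF slices found in ", path)
    fs
  } else path
  first <- tiff::readTIFF(paths[[1]], info = TRUE, as.is = TRUE)
  bits <- attr(first, "bits.per.sample")
  if (is.null(dtype_bits)) dtype_bits <- if (is.null(bits)) 32L else bits
  dtype_bits <- as.integer(dtype_bits)
  sidecar <- paste0(path, ".json")
  enc <- if (dtype_bits %in% c(8L, 16L))
    list(mode = "uint", bits = dtype_bits)
  else if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else list(mode = "raw01", bits = 32L)   # external float TIFF
  slabs <- lapply(paths, read_tiff_zyx, enc = enc)
  nz <- sum(vapply(slabs, function(s) dim(s)[1], 0))
  arr <- array(0, c(nz, dim(slabs[[1]])[2], dim(slabs[[1]])[3]))
  z <- 1L
  for (s in slabs) {
    arr[z:(z + dim(s)[1] - 1L), , ] <- s
    z <- z + dim(s)[1]
  }
  ct_volume(arr, voxel_size_um = voxel_size_um, dtype_bits = dtype_bits)
}

#' Write a volume as a multi-page TIFF
#'
#' @param volume a [ct_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  volume <- as_volume(volume)
  enc <- encoding_for(volume$dtype_bits, min(volume$data), max(volume$data))
  write_tiff_zyx(volume$data, path, enc)
  ## 32-bit files need the encoding to be re-readable; record it alongside
  if (enc$bits == 32L)
    jsonlite::write_json(enc, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

## Dice overlap between two binary masks
#' Dice coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks of equal geometry.
#' Returns 1 when both masks are empty.
#'
#' @param a,b binary arrays (0/1 or logical) of identical dimension.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("geometry mismatch")
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
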