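## Slice-wise 2D filter bank: raw intensity plus Gaussian pre-blur,
## Neighbors, Entropy, structure-tensor and Hessian eigenvalue features.
## These are the inputs to the voxel classifier; no histogram normalization
## or equalization is ever applied, because voxel values are proportional to
## X-ray density and rescaling would destroy comparability across blocks and
## scans.

#' Filter-bank configuration
#'
#' Declarative description of the per-voxel feature bank. The feature count,
#' names and order are a deterministic function of the spec, so a classifier
#' trained with one spec can refuse feature stacks built with another (see
#' [spec_fingerprint()]).
#'
#' Default scales are chosen to span wall thicknesses of a few voxels at
#' 8 um resolution: Gaussian sigmas 1-8, neighbor shifts 1-2, an entropy
#' disc of radius 4 with 64 gray bins, structure-tensor
#' (derivative, integration) scale pairs up to (2,3), Hessian sigmas 1-4.
#'
#' @param gaussian_sigmas positive Gaussian pre-blur scales (voxels).
#' @param neighbors_radii positive integer shift radii.
#' @param entropy_radius disc radius for the local entropy window.
#' @param entropy_bins number of intensity quantization bins (>= 2).
#' @param structure_scales list of `(derivative_scale, integration_scale)`
#'   pairs.
#' @param hessian_sigmas positive second-derivative scales.
#' @param enabled subset of
#'   `c("gaussian", "neighbors", "entropy", "structure", "hessian")`.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(gaussian_sigmas = c(1, 2, 4, 8),
                         neighbors_radii = c(1L, 2L),
                         entropy_radius = 4L, entropy_bins = 64L,
                         structure_scales = list(c(1, 1), c(1, 3), c(2, 3)),
                         hessian_sigmas = c(1, 2, 4),
                         enabled = c("gaussian", "neighbors", "entropy",
                                     "structure", "hessian")) {
  if (length(enabled) == 0L) stop("at least one filter must be enabled")
  enabled <- match.arg(enabled, c("gaussian", "neighbors", "entropy",
                                  "structure", "hessian"),
                       several.ok = TRUE)
  if ("gaussian" %in% enabled && any(gaussian_sigmas <= 0))
    stop("gaussian sigmas must be positive")
  if ("neighbors" %in% enabled && any(neighbors_radii < 1))
    stop("neighbor radii must be >= 1")
  if ("entropy" %in% enabled && (entropy_radius < 1 || entropy_bins < 2))
    stop("entropy radius must be >= 1 and bins >= 2")
  if ("structure" %in% enabled &&
      any(vapply(structure_scales, function(p) any(p <= 0), TRUE)))
    stop("structure scales must be positive")
  if ("hessian" %in% enabled && any(hessian_sigmas <= 0))
    stop("hessian sigmas must be positive")
  structure(list(gaussian_sigmas = gaussian_sigmas,
                 neighbors_radii = as.integer(neighbors_radii),
                 entropy_radius = as.integer(entropy_radius),
                 entropy_bins = as.integer(entropy_bins),
                 structure_scales = structure_scales,
                 hessian_sigmas = hessian_sigmas,
                 enabled = enabled),
            class = "feature_spec")
}

## compass order is fixed: N, NE, E, SE, S, SW, W, NW with y increasing
## downward, so N = (dy -1, dx 0)
.compass <- list(N  = c(-1L, 0L), NE = c(-1L, 1L), E  = c(0L, 1L),
                 SE = c(1L, 1L),  S  = c(1L, 0L),  SW = c(1L, -1L),
                 W  = c(0L, -1L), NW = c(-1L, -1L))

#' Ordered feature names for a spec
#'
#' Raw intensity is always feature 1; enabled groups follow in the fixed
#' order gaussian, neighbors, entropy, structure, hessian.
#'
#' @param spec a [feature_spec()].
#' @return character vector of length [feature_count()].
#' @export
feature_names <- function(spec) {
  nm <- "raw"
  if ("gaussian" %in% spec$enabled)
    nm <- c(nm, sprintf("gaussian_s%g", spec$gaussian_sigmas))
  if ("neighbors" %in% spec$enabled)
    for (r in spec$neighbors_radii)
      nm <- c(nm, sprintf("neighbors_r%d_%s", r, names(.compass)))
  if ("entropy" %in% spec$enabled)
    nm <- c(nm, sprintf("entropy_r%d_b%d", spec$entropy_radius,
                        spec$entropy_bins))
  if ("structure" %in% spec$enabled)
    for (p in spec$structure_scales)
      nm <- c(nm, sprintf("structure_d%g_i%g_%s", p[1], p[2],
                          c("emax", "emin")))
  if ("hessian" %in% spec$enabled)
    nm <- c(nm, unlist(lapply(spec$hessian_sigmas, function(s)
      sprintf("hessian_s%g_%s", s, c("ehi", "elo", "orient")))))
  nm
}

#' Number of features a spec produces
#' @param spec a [feature_spec()].
#' @return integer feature count.
#' @export
feature_count <- function(spec) length(feature_names(spec))

#' Fingerprint of a feature spec
#'
#' Canonical string over all fields; training records it and prediction
#' refuses a mismatching spec.
#'
#' @param spec a [feature_spec()].
#' @return character scalar.
#' @export
spec_fingerprint <- function(spec) {
  paste0("v1|g:", paste(spec$gaussian_sigmas, collapse = ","),
         "|n:", paste(spec$neighbors_radii, collapse = ","),
         "|e:", spec$entropy_radius, ",", spec$entropy_bins,
         "|s:", paste(vapply(spec$structure_scales,
                             function(p) paste(p, collapse = "-"), ""),
                      collapse = ","),
         "|h:", paste(spec$hessian_sigmas, collapse = ","),
         "|on:", paste(sort(spec$enabled), collapse = ","))
}

#' Maximum spatial footprint radius of a spec
#'
#' The largest half-width (in voxels) any enabled filter reads around a
#' pixel; a block halo at least this wide guarantees seam-free blockwise
#' feature computation.
#'
#' @param spec a [feature_spec()].
#' @return integer radius.
#' @export
feature_footprint <- function(spec) {
  r <- 0L
  if ("gaussian" %in% spec$enabled)
    r <- max(r, gauss_radius(max(spec$gaussian_sigmas)))
  if ("neighbors" %in% spec$enabled) r <- max(r, max(spec$neighbors_radii))
  if ("entropy" %in% spec$enabled) r <- max(r, spec$entropy_radius)
  if ("structure" %in% spec$enabled)
    r <- max(r, max(vapply(spec$structure_scales,
                           function(p) gauss_radius(p[1]) + gauss_radius(p[2]),
                           0L)))
  if ("hessian" %in% spec$enabled)
    r <- max(r, gauss_radius(max(spec$hessian_sigmas)))
  as.integer(r)
}

## ---- kernels --------------------------------------------------------------

gauss_radius <- function(sigma) max(1L, as.integer(ceiling(3 * sigma)))

gauss_kernel <- function(sigma, order = 0L) {
  r <- gauss_radius(sigma)
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2))
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    k <- t * g                      # response to a unit ramp normalised to 1
    return(k / sum(t * k))
  }
  if (order == 2L) {
    k <- (t^2 - sigma^2) * g
    k <- k - mean(k)                # zero response to constants
    return(k * 2 / sum(t^2 * k))   # response to x^2/2 normalised to 1
  }
  stop("derivative order must be 0, 1 or 2")
}

as_slice <- function(slice) {
  if (is.null(dim(slice)) || length(dim(slice)) != 2L)
    stop("slice must be a 2D matrix (y, x)")
  storage.mode(slice) <- "double"
  slice
}

#' Gaussian blur of a 2D slice
#'
#' Separable Gaussian smoothing with mirror-reflected boundaries. The
#' kernel is truncated at 3 sigma and normalised, so constants (and the
#' slice mean) are preserved.
#'
#' @param slice 2D matrix (y, x).
#' @param sigma positive blur scale in pixels.
#' @return smoothed matrix of the same shape.
#' @export
gaussian_blur <- function(slice, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a positive scalar")
  k <- gauss_kernel(sigma)
  cpp_sep_conv2(as_slice(slice), k, k)
}

#' Neighbors features: compass-shifted copies of the slice
#'
#' For each radius `r`, eight features sample the slice at distance `r` in
#' the compass directions N, NE, E, SE, S, SW, W, NW (y increases
#' downward): `feature_d(y, x) = slice(y + r*dy_d, x + r*dx_d)` with mirror
#' boundary. A bright pixel therefore appears displaced *against* the
#' direction: in the "N" feature of radius 1, a pixel at (10,10) shows up
#' at (11,10).
#'
#' @param slice 2D matrix (y, x).
#' @param radii positive integer shift radii.
#' @return list of matrices named as in [feature_names()].
#' @export
neighbors_features <- function(slice, radii = c(1L, 2L)) {
  slice <- as_slice(slice)
  if (any(radii < 1)) stop("radii must be >= 1")
  ny <- nrow(slice); nx <- ncol(slice)
  out <- list()
  for (r in as.integer(radii)) {
    for (d in names(.compass)) {
      dy <- .compass[[d]][1] * r; dx <- .compass[[d]][2] * r
      iy <- vapply(seq_len(ny) - 1L + dy, reflect_r, 0L, n = ny) + 1L
      ix <- vapply(seq_len(nx) - 1L + dx, reflect_r, 0L, n = nx) + 1L
      out[[sprintf("neighbors_r%d_%s", r, d)]] <- slice[iy, ix, drop = FALSE]
    }
  }
  out
}

#' Local entropy features
#'
#' Per-pixel Shannon entropy (base 2) of the intensity histogram over a
#' disc of the given radius, after quantising intensities to `bins`
#' equal-width bins. By default the quantization range is the slice's
#' min-max; pass the volume-global range (from the store sidecar) via
#' `range` to make blockwise computation consistent with the whole volume.
#' A degenerate range yields zero entropy everywhere.
#'
#' @param slice 2D matrix (y, x).
#' @param radius disc radius >= 1.
#' @param bins quantization bins >= 2.
#' @param range optional `c(lo, hi)` quantization range.
#' @return matrix of entropies in bits.
#' @export
entropy_features <- function(slice, radius = 4L, bins = 64L, range = NULL) {
  slice <- as_slice(slice)
  if (radius < 1) stop("`radius` must be >= 1")
  if (bins < 2) stop("`bins` must be >= 2")
  if (is.null(range)) range <- c(min(slice), max(slice))
  cpp_entropy2d(slice, as.integer(radius), as.integer(bins),
                range[1], range[2])
}

eig2_sym <- function(a, b, c) {
  tr2 <- (a + c) / 2
  disc <- sqrt(((a - c) / 2)^2 + b^2)
  list(hi = tr2 + disc, lo = tr2 - disc)
}

#' Structure-tensor eigenvalue features
#'
#' Gaussian-derivative gradients at `derivative_scale` form the outer
#' product tensor, which is smoothed at `integration_scale`; the two
#' eigenvalues of the smoothed 2x2 tensor measure local edge strength and
#' anisotropy (both are >= 0; edges show a large/small split, corners two
#' large values).
#'
#' @param slice 2D matrix (y, x).
#' @param derivative_scale,integration_scale positive Gaussian scales.
#' @return list with matrices `emax`, `emin`.
#' @export
structure_features <- function(slice, derivative_scale = 1,
                               integration_scale = 1) {
  if (derivative_scale <= 0 || integration_scale <= 0)
    stop("scales must be positive")
  slice <- as_slice(slice)
  g0 <- gauss_kernel(derivative_scale, 0L)
  g1 <- gauss_kernel(derivative_scale, 1L)
  gx <- cpp_sep_conv2(slice, g0, g1)   # derivative along x (columns)
  gy <- cpp_sep_conv2(slice, g1, g0)   # derivative along y (rows)
  gi <- gauss_kernel(integration_scale, 0L)
  jxx <- cpp_sep_conv2(gx * gx, gi, gi)
  jxy <- cpp_sep_conv2(gx * gy, gi, gi)
  jyy <- cpp_sep_conv2(gy * gy, gi, gi)
  ev <- eig2_sym(jxx, jxy, jyy)
  list(emax = ev$hi, emin = ev$lo)
}

#' Hessian eigenvalue and orientation features
#'
#' Eigenvalues of the Gaussian second-derivative Hessian, ordered by signed
#' value (`ehi >= elo`), plus the orientation of the eigenvector belonging
#' to the larger-magnitude eigenvalue, as an angle in `[0, pi)` measured
#' from the +x axis. Bright tube walls one to a few voxels wide produce a
#' strongly negative eigenvalue across the wall, which is why this filter
#' is a classic tubular-structure detector; orientation is 0 by convention
#' at eigenvalue ties.
#'
#' @param slice 2D matrix (y, x).
#' @param sigma positive derivative scale.
#' @return list with matrices `ehi`, `elo`, `orient`.
#' @export
hessian_features <- function(slice, sigma = 1) {
  if (sigma <= 0) stop("`sigma` must be positive")
  slice <- as_slice(slice)
  g0 <- gauss_kernel(sigma, 0L)
  g1 <- gauss_kernel(sigma, 1L)
  g2 <- gauss_kernel(sigma, 2L)
  hxx <- cpp_sep_conv2(slice, g0, g2)
  hyy <- cpp_sep_conv2(slice, g2, g0)
  hxy <- cpp_sep_conv2(slice, g1, g1)
  ev <- eig2_sym(hxx, hxy, hyy)
  ## eigenvector of the larger-|.| eigenvalue; A = [[hxx, hxy], [hxy, hyy]]
  lam <- ifelse(abs(ev$hi) >= abs(ev$lo), ev$hi, ev$lo)
  vx <- hxy
  vy <- lam - hxx
  deg <- abs(vx) < 1e-12 & abs(vy) < 1e-12   # hxy ~ 0 and lam ~ hxx
  ## diagonal case: eigenvector is an axis; (1,0) if lam matches hxx
  vx[deg] <- ifelse(abs(lam - hxx)[deg] <= abs(lam - hyy)[deg], 1, 0)
  vy[deg] <- 1 - vx[deg]
  th <- atan2(vy, vx) %% pi
  tie <- abs(ev$hi - ev$lo) < 1e-12
  th[tie] <- 0
  list(ehi = ev$hi, elo = ev$lo, orient = th)
}

#' Build the per-voxel feature stack
#'
#' Computes all enabled features for a 2D slice or, slice-by-slice along z,
#' for a 3D block. Raw intensity is always feature 1 and the order is the
#' stable order of [feature_names()]. No normalization or equalization is
#' applied at any point.
#'
#' @param block 2D matrix (y, x) or 3D array (z, y, x).
#' @param spec a [feature_spec()].
#' @param intensity_range optional global `c(lo, hi)` used for entropy
#'   quantization (see [entropy_features()]).
#' @return list with `values` (voxels x features matrix, voxel order =
#'   column-major within each slice, slices stacked along z), `names`,
#'   `fingerprint`, `dim`.
#' @export
build_feature_stack <- function(block, spec, intensity_range = NULL) {
  if (!inherits(spec, "feature_spec")) stop("`spec` must be a feature_spec")
  d <- dim(block)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    stop("`block` must be a 2D slice or 3D block")
  slices <- if (length(d) == 2L) list(as_slice(block))
            else lapply(seq_len(d[1]), function(z)
              as_slice(array(block[z, , ], d[2:3])))
  nm <- feature_names(spec)
  vals <- do.call(rbind, lapply(slices, function(s) {
    cols <- list(raw = as.vector(s))
    if ("gaussian" %in% spec$enabled)
      for (sg in spec$gaussian_sigmas)
        cols[[sprintf("gaussian_s%g", sg)]] <- as.vector(gaussian_blur(s, sg))
    if ("neighbors" %in% spec$enabled)
      cols <- c(cols, lapply(neighbors_features(s, spec$neighbors_radii),
                             as.vector))
    if ("entropy" %in% spec$enabled)
      cols[[sprintf("entropy_r%d_b%d", spec$entropy_radius,
                    spec$entropy_bins)]] <-
        as.vector(entropy_features(s, spec$entropy_radius, spec$entropy_bins,
                                   range = intensity_range))
    if ("structure" %in% spec$enabled)
      for (p in spec$structure_scales) {
        st <- structure_features(s, p[1], p[2])
        cols[[sprintf("structure_d%g_i%g_emax", p[1], p[2])]] <-
          as.vector(st$emax)
        cols[[sprintf("structure_d%g_i%g_emin", p[1], p[2])]] <-
          as.vector(st$emin)
      }
    if ("hessian" %in% spec$enabled)
      for (sg in spec$hessian_sigmas) {
        h <- hessian_features(s, sg)
        cols[[sprintf("hessian_s%g_ehi", sg)]] <- as.vector(h$ehi)
        cols[[sprintf("hessian_s%g_elo", sg)]] <- as.vector(h$elo)
        cols[[sprintf("hessian_s%g_orient", sg)]] <- as.vector(h$orient)
      }
    do.call(cbind, cols[nm])
  }))
  colnames(vals) <- nm
  list(values = vals, names = nm, fingerprint = spec_fingerprint(spec),
       dim = d)
}
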