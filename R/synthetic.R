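## Synthetic micro-CT phantoms: a wax background, darker air bubbles, a
## textured alveolar region, and tubes with bright walls whose lumen
## intensity equals the wax background (wax fills both the block and the
## vessel interiors). Ground-truth wall/lumen masks come with every
## phantom, so each pipeline stage is testable without real scan data.

#' Phantom scene specification
#'
#' Intensities default to 16-bit-range values (wax 20000, wall 35000,
#' bubble 8000) so the 8-, 16- and 32-bit storage paths are all exercised
#' by casting; the ordering `wall > wax > bubble` mirrors X-ray density of
#' tissue, paraffin and air.
#'
#' @param dims volume dims `(nz, ny, nx)`.
#' @param wax_level,wall_level,bubble_level intensities with
#'   `wall_level > wax_level > bubble_level`.
#' @param tubes list of tubes, each
#'   `list(points = m x 3 matrix of (z, y, x) control points,
#'   lumen_radius, wall_thickness)`; centerlines are polylines with linear
#'   interpolation.
#' @param bubbles list of `list(center = c(z, y, x), radius)` spheres.
#' @param alveolar optional `list(box = 3 x 2 matrix of half-open (lo, hi)
#'   ranges, amplitude)` textured region.
#' @param noise_sigma additive Gaussian noise sd (reconstruction-noise
#'   proxy).
#' @param seed RNG seed for noise and texture.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(96L, 96L, 96L),
                         wax_level = 20000, wall_level = 35000,
                         bubble_level = 8000,
                         tubes = list(), bubbles = list(), alveolar = NULL,
                         noise_sigma = 0, seed = 1L) {
  if (!(wall_level > wax_level && wax_level > bubble_level))
    stop("intensity ordering wall_level > wax_level > bubble_level required")
  for (tb in tubes) {
    if (tb$wall_thickness < 1) stop("wall_thickness must be >= 1")
    if (tb$lumen_radius < 0) stop("lumen_radius must be >= 0")
  }
  structure(list(dims = as.integer(dims), wax_level = wax_level,
                 wall_level = wall_level, bubble_level = bubble_level,
                 tubes = tubes, bubbles = bubbles, alveolar = alveolar,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

## min distance from every voxel centre to a polyline (m x 3 control points)
polyline_distance <- function(coords, points) {
  dmin <- rep(Inf, nrow(coords))
  for (s in seq_len(nrow(points) - 1L)) {
    a <- points[s, ]; b <- points[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    pa <- sweep(coords, 2, a)
    t <- if (len2 == 0) rep(0, nrow(coords)) else
      pmin(pmax((pa %*% ab)[, 1] / len2, 0), 1)
    dz <- pa[, 1] - t * ab[1]
    dy <- pa[, 2] - t * ab[2]
    dx <- pa[, 3] - t * ab[3]
    dmin <- pmin(dmin, sqrt(dz^2 + dy^2 + dx^2))
  }
  dmin
}

#' Render a phantom
#'
#' Paints, in order: wax background, alveolar texture, tubes (lumen at wax
#' level — the inside of a vessel matches the background — and wall at wall
#' level), air bubbles (override everything), then seeded additive Gaussian
#' noise. Ground-truth wall and lumen masks are computed before noise and
#' exclude bubble-overridden voxels. Tubes reaching outside the volume are
#' clipped with a warning.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [ct_volume()], 16-bit), `wall_truth` and
#'   `lumen_truth` (binary arrays).
#' @export
render_phantom <- function(spec) {
  d <- spec$dims
  vol <- array(spec$wax_level, d)
  set.seed(spec$seed)

  if (!is.null(spec$alveolar)) {
    box <- spec$alveolar$box
    bz <- (box[1, 1] + 1):box[1, 2]
    by <- (box[2, 1] + 1):box[2, 2]
    bx <- (box[3, 1] + 1):box[3, 2]
    tex <- array(runif(length(bz) * length(by) * length(bx), -1, 1),
                 c(length(bz), length(by), length(bx)))
    for (z in seq_along(bz))       # mild smoothing: correlated texture
      tex[z, , ] <- gaussian_blur(array(tex[z, , ], dim(tex)[2:3]), 1.2)
    vol[bz, by, bx] <- spec$wax_level +
      spec$alveolar$amplitude * tex / max(abs(tex))
  }

  grid <- as.matrix(expand.grid(z = seq_len(d[1]) - 1L,
                                y = seq_len(d[2]) - 1L,
                                x = seq_len(d[3]) - 1L))
  wall <- array(0L, d); lumen <- array(0L, d)
  for (tb in spec$tubes) {
    pts <- tb$points
    if (any(pts < -0.5) || any(sweep(pts, 2, d - 0.5) > 0))
      warning("tube centerline reaches outside the volume; geometry clipped")
    dist <- polyline_distance(grid, pts)
    rin <- tb$lumen_radius
    rout <- tb$lumen_radius + tb$wall_thickness
    li <- dist <= rin
    wi <- dist > rin & dist <= rout
    lumen[li] <- 1L
    wall[wi] <- 1L
    vol[li] <- spec$wax_level     # lumen matches the background
    vol[wi] <- spec$wall_level
  }
  ## overlapping tubes: a voxel inside any lumen is lumen, not wall
  wall[lumen == 1L] <- 0L

  for (bb in spec$bubbles) {
    ctr <- bb$center
    bi <- (grid[, 1] - ctr[1])^2 + (grid[, 2] - ctr[2])^2 +
          (grid[, 3] - ctr[3])^2 <= bb$radius^2
    vol[bi] <- spec$bubble_level
    wall[bi] <- 0L; lumen[bi] <- 0L
  }

  if (spec$noise_sigma > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sigma), d)
  ## a 16-bit reconstruction holds integer counts
  vol <- round(pmax(vol, 0))

  list(volume = ct_volume(vol, voxel_size_um = 8, dtype_bits = 16L),
       wall_truth = wall, lumen_truth = lumen)
}

#' Default validation phantom
#'
#' A 96^3 scene with two curved tubes — a wider "airway" (lumen 7, wall 2)
#' and a narrower "vessel" (lumen 4, wall 2) — three air bubbles, one
#' textured alveolar box, and noise at 10% of the wall-wax contrast. This
#' is the study scene used throughout the package's tests: a reduced-count
#' analogue of annotating a couple of airways and vessels against
#' representative background areas.
#'
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
default_phantom <- function(seed = 1L) {
  phantom_spec(
    dims = c(96L, 96L, 96L),
    tubes = list(
      list(points = rbind(c(0, 30, 22), c(32, 42, 35), c(64, 38, 52),
                          c(95, 28, 68)),
           lumen_radius = 7, wall_thickness = 2),
      list(points = rbind(c(18, 72, 0), c(45, 64, 30), c(60, 70, 62),
                          c(78, 78, 95)),
           lumen_radius = 4, wall_thickness = 2)),
    bubbles = list(list(center = c(20, 14, 78), radius = 5),
                   list(center = c(70, 18, 14), radius = 4),
                   list(center = c(86, 82, 18), radius = 6)),
    alveolar = list(box = rbind(c(56L, 90L), c(6L, 36L), c(56L, 90L)),
                    amplitude = 6000),
    noise_sigma = 0.1 * (35000 - 20000),
    seed = seed)
}

#' Sample a label set from phantom ground truth
#'
#' Stands in for manual annotation: on `n_slices` slices (chosen among
#' slices with enough foreground), samples foreground labels from the
#' wall-plus-lumen truth — annotating the whole cross-section including the
#' wax-filled interior gives the classifier its easiest-to-learn edges —
#' and background labels from everywhere else. Deterministic given `seed`.
#'
#' @param wall_truth,lumen_truth binary truth arrays from
#'   [render_phantom()].
#' @param n_slices number of training slices (default 2).
#' @param n_per_class samples per class per slice (default 200).
#' @param seed RNG seed.
#' @return A [label_set()].
#' @export
make_labelset_from_truth <- function(wall_truth, lumen_truth,
                                     n_slices = 2L, n_per_class = 200L,
                                     seed = 1L) {
  if (n_slices < 1L) stop("`n_slices` must be >= 1")
  fg <- (wall_truth == 1L) | (lumen_truth == 1L)
  d <- dim(fg)
  set.seed(seed)
  fg_per_slice <- vapply(seq_len(d[1]), function(z) sum(fg[z, , ]), 0)
  eligible <- which(fg_per_slice >= min(50, max(fg_per_slice)))
  if (length(eligible) == 0L) stop("no slice contains foreground")
  if (length(eligible) < n_slices) {
    warning("fewer foreground-rich slices than requested; resampling")
    zs <- sample(eligible, n_slices, replace = TRUE)
  } else zs <- sample(eligible, n_slices)
  out <- list()
  for (z in zs) {
    sl <- fg[z, , ]
    wf <- which(sl); wb <- which(!sl)
    sf <- sample(wf, min(n_per_class, length(wf)))
    sb <- sample(wb, min(n_per_class, length(wb)))
    yx <- function(lin) cbind(y = (lin - 1L) %% d[2],
                              x = (lin - 1L) %/% d[2])
    f <- yx(sf); b <- yx(sb)
    out[[length(out) + 1L]] <- data.frame(
      z = z - 1L, y = c(f[, "y"], b[, "y"]), x = c(f[, "x"], b[, "x"]),
      class = c(rep(1L, nrow(f)), rep(0L, nrow(b))))
  }
  df <- do.call(rbind, out)
  label_set(df$z, df$y, df$x, df$class)
}
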