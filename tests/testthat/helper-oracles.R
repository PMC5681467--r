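# Independent brute-force oracles used to check the fast implementations.
# All of these are written naively (loops, dense kernels, flood fill) on
# purpose: they share no code with the package internals they verify.

# reflect-with-edge-duplication index, 0-based
oracle_reflect <- function(p, n) {
  while (p < 0 || p >= n) {
    if (p < 0) p <- -1 - p
    if (p >= n) p <- 2 * n - 1 - p
  }
  p
}

# dense 2D correlation with a centred kernel, reflected boundary
oracle_conv2 <- function(slice, kernel) {
  ny <- nrow(slice); nx <- ncol(slice)
  ky <- nrow(kernel); kx <- ncol(kernel)
  cy <- (ky - 1) / 2; cx <- (kx - 1) / 2
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    acc <- 0
    for (a in seq_len(ky)) for (b in seq_len(kx)) {
      yy <- oracle_reflect(y - 1 + a - 1 - cy, ny) + 1
      xx <- oracle_reflect(x - 1 + b - 1 - cx, nx) + 1
      acc <- acc + kernel[a, b] * slice[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

# sampled Gaussian / derivative kernels, truncated at 3 sigma, matching the
# documented normalisations (sum 1; unit ramp response; unit response to
# the second derivative of x^2/2)
oracle_gauss_kernel <- function(sigma, order = 0) {
  r <- max(1, ceiling(3 * sigma))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2))
  if (order == 0) return(g / sum(g))
  if (order == 1) { k <- t * g; return(k / sum(t * k)) }
  k <- (t^2 - sigma^2) * g
  k <- k - mean(k)
  k * 2 / sum(t^2 * k)
}

# per-pixel histogram entropy over a disc window
oracle_entropy <- function(slice, radius, bins) {
  ny <- nrow(slice); nx <- ncol(slice)
  lo <- min(slice); hi <- max(slice)
  out <- matrix(0, ny, nx)
  if (hi <= lo) return(out)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    vals <- numeric(nrow(offs))
    for (t in seq_len(nrow(offs))) {
      yy <- oracle_reflect(y - 1 + offs$dy[t], ny) + 1
      xx <- oracle_reflect(x - 1 + offs$dx[t], nx) + 1
      vals[t] <- slice[yy, xx]
    }
    b <- pmin(floor((vals - lo) / (hi - lo) * bins), bins - 1)
    p <- table(b) / length(b)
    out[y, x] <- -sum(p * log2(p))
  }
  out
}

# flood-fill connected components (repeated neighbour expansion)
oracle_label3d <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (lin in which(mask == 1)) {
    if (lab[lin] != 0L) next
    nxt <- nxt + 1L
    frontier <- lin
    lab[lin] <- nxt
    while (length(frontier) > 0) {
      nf <- integer()
      for (f in frontier) {
        z <- (f - 1) %% d[1] + 1
        y <- ((f - 1) %/% d[1]) %% d[2] + 1
        x <- (f - 1) %/% (d[1] * d[2]) + 1
        for (t in seq_len(nrow(offs))) {
          zz <- z + offs$dz[t]; yy <- y + offs$dy[t]; xx <- x + offs$dx[t]
          if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
              xx < 1 || xx > d[3]) next
          j <- zz + d[1] * (yy - 1) + d[1] * d[2] * (xx - 1)
          if (mask[j] == 1 && lab[j] == 0L) { lab[j] <- nxt; nf <- c(nf, j) }
        }
      }
      frontier <- nf
    }
  }
  lab
}

# separable box-mean / box-sum with reflected boundary (whole-volume
# reference for the halo-equivalence checks)
box_filter3 <- function(a, r, normalise = TRUE) {
  d <- dim(a)
  refl <- function(p, n) {
    while (any(bad <- p < 1 | p > n)) {
      p[p < 1] <- 1 - p[p < 1]
      p[p > n] <- 2 * n + 1 - p[p > n]
    }
    p
  }
  for (ax in 1:3) {
    acc <- array(0, d)
    for (t in -r:r) {
      idx <- refl(seq_len(d[ax]) + t, d[ax])
      acc <- acc + switch(ax, a[idx, , , drop = FALSE],
                          a[, idx, , drop = FALSE],
                          a[, , idx, drop = FALSE])
    }
    a <- if (normalise) acc / (2 * r + 1) else acc
  }
  a
}

# small seeded integer-valued volume
rand_volume <- function(dims, bits = 16L, seed = 1) {
  set.seed(seed)
  ct_volume(array(sample.int(2^min(bits, 16), prod(dims), replace = TRUE) - 1,
                  dims), dtype_bits = bits)
}

# light feature bank used where test runtime matters more than scale coverage
light_spec <- function() {
  feature_spec(gaussian_sigmas = c(1, 2), neighbors_radii = 1L,
               entropy_radius = 2L, entropy_bins = 16L,
               structure_scales = list(c(1, 1)), hessian_sigmas = 1)
}

# small two-tube phantom for fast classifier tests
small_phantom <- function(seed = 1, dims = c(48L, 48L, 48L),
                          noise_sigma = 1500) {
  phantom_spec(
    dims = dims,
    tubes = list(
      list(points = rbind(c(0, 16, 12), c(24, 22, 24), c(47, 16, 36)),
           lumen_radius = 5, wall_thickness = 2),
      list(points = rbind(c(8, 36, 0), c(30, 32, 24), c(40, 38, 47)),
           lumen_radius = 3, wall_thickness = 2)),
    bubbles = list(list(center = c(10, 8, 40), radius = 3)),
    noise_sigma = noise_sigma, seed = seed)
}
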