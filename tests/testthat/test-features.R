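test_that("gaussian blur is normalised, mean-preserving and matches dense
           convolution", {
  const <- matrix(7.5, 20, 20)
  expect_equal(gaussian_blur(const, 2), const, tolerance = 1e-12)

  imp <- matrix(0, 25, 25); imp[13, 13] <- 1
  expect_equal(sum(gaussian_blur(imp, 2)), 1, tolerance = 1e-6)

  set.seed(21)
  s <- matrix(runif(30 * 28, 0, 1000), 30, 28)
  k1 <- oracle_gauss_kernel(1.5)
  expect_equal(gaussian_blur(s, 1.5), oracle_conv2(s, outer(k1, k1)),
               tolerance = 1e-10)
  # mirror boundary with a symmetric kernel preserves the mean
  expect_equal(mean(gaussian_blur(s, 3)), mean(s), tolerance = 1e-6)
  expect_error(gaussian_blur(s, 0), "positive")
})

test_that("neighbors features shift by the documented compass convention", {
  const <- matrix(3, 12, 12)
  nf <- neighbors_features(const, c(1, 2))
  expect_length(nf, 16L)
  for (f in nf) expect_true(all(f == 3))

  s <- matrix(0, 30, 30); s[11, 11] <- 1   # bright pixel at (y,x) = (10,10)
  n1 <- neighbors_features(s, 1)
  expect_equal(which(n1$neighbors_r1_N == 1, arr.ind = TRUE)[1, ],
               c(row = 12, col = 11))  # appears at (11,10)
  expect_equal(which(n1$neighbors_r1_E == 1, arr.ind = TRUE)[1, ],
               c(row = 11, col = 10))  # displaced against east: at (10,9)

  # opposite shifts compose to the identity in the interior
  set.seed(4)
  r <- matrix(runif(400), 20, 20)
  n <- neighbors_features(r, 1)
  back <- neighbors_features(n$neighbors_r1_N, 1)$neighbors_r1_S
  expect_equal(back[2:19, 2:19], r[2:19, 2:19])
})

test_that("entropy features match the brute-force histogram oracle", {
  expect_true(all(entropy_features(matrix(5, 15, 15), 3, 16) == 0))

  # checkerboard: a radius-2 disc holds 9 of one value and 4 of the other
  cb <- outer(1:20, 1:20, function(y, x) (y + x) %% 2) * 100
  expected <- -(9 / 13 * log2(9 / 13) + 4 / 13 * log2(4 / 13))
  expect_equal(entropy_features(cb, 2, 8)[10, 10], expected,
               tolerance = 1e-12)

  set.seed(31)
  s <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_equal(entropy_features(s, 3, 16), oracle_entropy(s, 3, 16),
               tolerance = 1e-10)
  expect_error(entropy_features(s, 0, 16), "radius")
  expect_error(entropy_features(s, 3, 1), "bins")
})

test_that("structure-tensor eigenvalues match brute-force assembly and are
           rotation-equivariant", {
  const <- matrix(2, 16, 16)
  sf <- structure_features(const, 1, 1)
  expect_true(all(abs(sf$emax) < 1e-10) && all(abs(sf$emin) < 1e-10))

  # vertical step edge: ridge of emax along the edge, emin ~ 0 there
  step <- matrix(0, 31, 31); step[, 16:31] <- 100
  se <- structure_features(step, 1, 1)
  expect_gt(se$emax[15, 16], 100)
  expect_lt(se$emin[15, 16] / se$emax[15, 16], 0.05)

  # brute-force oracle on a seeded random slice
  set.seed(41)
  s <- matrix(runif(32 * 32, 0, 100), 32, 32)
  g0 <- oracle_gauss_kernel(1); g1 <- oracle_gauss_kernel(1, 1)
  gx <- oracle_conv2(s, outer(g0, g1))
  gy <- oracle_conv2(s, outer(g1, g0))
  gi <- oracle_gauss_kernel(2)
  jxx <- oracle_conv2(gx * gx, outer(gi, gi))
  jxy <- oracle_conv2(gx * gy, outer(gi, gi))
  jyy <- oracle_conv2(gy * gy, outer(gi, gi))
  emax <- matrix(0, 32, 32); emin <- matrix(0, 32, 32)
  for (i in seq_len(32)) for (j in seq_len(32)) {
    ev <- eigen(matrix(c(jxx[i, j], jxy[i, j], jxy[i, j], jyy[i, j]), 2),
                symmetric = TRUE, only.values = TRUE)$values
    emax[i, j] <- ev[1]; emin[i, j] <- ev[2]
  }
  got <- structure_features(s, 1, 2)
  expect_equal(got$emax, emax, tolerance = 1e-5)
  expect_equal(got$emin, emin, tolerance = 1e-5)

  # rotating the slice by 90 degrees rotates the eigenvalue maps
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  a <- structure_features(rot90(s), 1, 2)
  b <- lapply(structure_features(s, 1, 2), rot90)
  inner <- 6:27
  expect_equal(a$emax[inner, inner], b$emax[inner, inner], tolerance = 1e-5)
  expect_equal(a$emin[inner, inner], b$emin[inner, inner], tolerance = 1e-5)
})

test_that("hessian eigen-decomposition matches brute force; ridges give a
           negative eigenvalue across the ridge", {
  const <- matrix(1, 16, 16)
  h0 <- hessian_features(const, 1)
  expect_true(all(abs(h0$ehi) < 1e-10) && all(abs(h0$elo) < 1e-10))
  expect_true(all(h0$orient == 0))

  # bright one-pixel horizontal ridge
  ridge <- matrix(0, 31, 31); ridge[16, ] <- 100
  h <- hessian_features(ridge, 1)
  expect_lt(h$elo[16, 15], -20)
  # orientation of the strong eigenvector ~ the ridge normal (+y, 90 deg)
  expect_lt(abs(h$orient[16, 15] - pi / 2), 5 * pi / 180)

  set.seed(51)
  s <- matrix(runif(32 * 32, 0, 100), 32, 32)
  g0 <- oracle_gauss_kernel(1.5); g1 <- oracle_gauss_kernel(1.5, 1)
  g2 <- oracle_gauss_kernel(1.5, 2)
  hxx <- oracle_conv2(s, outer(g0, g2))
  hyy <- oracle_conv2(s, outer(g2, g0))
  hxy <- oracle_conv2(s, outer(g1, g1))
  ehi <- matrix(0, 32, 32); elo <- matrix(0, 32, 32)
  for (i in seq_len(32)) for (j in seq_len(32)) {
    ev <- eigen(matrix(c(hxx[i, j], hxy[i, j], hxy[i, j], hyy[i, j]), 2),
                symmetric = TRUE, only.values = TRUE)$values
    ehi[i, j] <- ev[1]; elo[i, j] <- ev[2]
  }
  got <- hessian_features(s, 1.5)
  expect_equal(got$ehi, ehi, tolerance = 1e-5)
  expect_equal(got$elo, elo, tolerance = 1e-5)
})

test_that("feature stacks have stable order, documented counts and are
           deterministic", {
  spec <- feature_spec()
  # 1 raw + 4 gaussian + 2*8 neighbors + 1 entropy + 3*2 structure + 3*3 hessian
  expect_identical(feature_count(spec), 37L)
  expect_identical(feature_names(spec)[1], "raw")

  only_g <- feature_spec(gaussian_sigmas = 2, enabled = "gaussian")
  expect_identical(feature_count(only_g), 2L)

  set.seed(61)
  blk <- array(runif(8 * 16 * 16, 0, 100), c(8, 16, 16))
  fs1 <- build_feature_stack(blk, light_spec())
  fs2 <- build_feature_stack(blk, light_spec())
  expect_identical(fs1$values, fs2$values)
  expect_identical(dim(fs1$values), c(8L * 16L * 16L, feature_count(light_spec())))

  expect_error(feature_spec(enabled = character()), "at least one")
  expect_false(spec_fingerprint(spec) == spec_fingerprint(light_spec()))
})

test_that("features are translation-equivariant in the slice interior", {
  set.seed(71)
  base <- matrix(runif(40 * 40, 0, 100), 40, 40)
  shifted <- base[c(3:40, 39, 38), ]  # shift up by 2 (content moves -y)
  spec <- feature_spec(gaussian_sigmas = 2, neighbors_radii = 1L,
                       entropy_radius = 2L, entropy_bins = 16L,
                       structure_scales = list(c(1, 1)), hessian_sigmas = 1,
                       enabled = c("gaussian", "neighbors", "structure",
                                   "hessian"))
  fa <- build_feature_stack(base, spec)
  fb <- build_feature_stack(shifted, spec)
  ga <- matrix(fa$values[, "gaussian_s2"], 40, 40)
  gb <- matrix(fb$values[, "gaussian_s2"], 40, 40)
  inner_y <- 10:28
  expect_equal(gb[inner_y, 10:30], ga[inner_y + 2, 10:30], tolerance = 1e-8)
  ha <- matrix(fa$values[, "hessian_s1_ehi"], 40, 40)
  hb <- matrix(fb$values[, "hessian_s1_ehi"], 40, 40)
  expect_equal(hb[inner_y, 10:30], ha[inner_y + 2, 10:30], tolerance = 1e-8)
})
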