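test_that("probability thresholding is monotone with >= semantics", {
  set.seed(1)
  p <- array(runif(6^3), c(6, 6, 6))
  expect_true(all(threshold_probability(p, 0) == 1))
  expect_identical(sum(threshold_probability(p, 1)), sum(p == 1))
  expect_error(threshold_probability(p, 1.0001), "\\[0, 1\\]")
  expect_error(threshold_probability(p, -0.1), "\\[0, 1\\]")

  m5 <- threshold_probability(p, 0.5)
  expect_identical(m5, (p >= 0.5) + 0L)
  # monotone chain: t1 <= t2 => mask(t2) subset of mask(t1)
  for (t2 in c(0.6, 0.8, 0.95))
    expect_true(all(threshold_probability(p, t2) <= m5 |
                    threshold_probability(p, t2) == 0))
})

test_that("intensity refinement removes wax-dark voxels and is contractive", {
  ph <- render_phantom(small_phantom(seed = 2, noise_sigma = 0))
  wall_lumen <- (ph$wall_truth | ph$lumen_truth) + 0L
  # t2 at the global minimum keeps everything
  expect_identical(refine_by_intensity(wall_lumen, ph$volume,
                                       min(ph$volume$data)),
                   wall_lumen)
  # t2 between wax and wall strips the lumen, keeps the wall
  ref <- refine_by_intensity(wall_lumen, ph$volume, 27500)
  expect_true(all(ref <= wall_lumen))
  expect_identical(sum(ref[ph$lumen_truth == 1]), 0L)
  expect_gte(sum(ref[ph$wall_truth == 1]) / sum(ph$wall_truth), 0.99)
  # t2 above the global maximum empties the mask
  expect_identical(sum(refine_by_intensity(wall_lumen, ph$volume,
                                           max(ph$volume$data) + 1)), 0L)
  expect_error(refine_by_intensity(wall_lumen[1:10, , ], ph$volume, 0),
               "mismatch")
})

test_that("connected components match a flood-fill oracle", {
  expect_identical(nrow(label_regions(array(0L, c(4, 4, 4)))$table), 0L)

  # corner-touching cubes: one region at 26-connectivity, two at 6
  m <- array(0L, c(8, 8, 8))
  m[1:3, 1:3, 1:3] <- 1L
  m[4:6, 4:6, 4:6] <- 1L
  expect_identical(nrow(label_regions(m, 26)$table), 1L)
  expect_identical(nrow(label_regions(m, 6)$table), 2L)
  expect_error(label_regions(m, 18), "connectivity")

  set.seed(13)
  for (conn in c(6L, 26L)) {
    sp <- array((runif(20^3) < 0.08) + 0L, c(20, 20, 20))
    got <- label_regions(sp, conn)
    ref <- oracle_label3d(sp, conn)
    # same partition: label images agree up to relabelling, sizes match
    expect_identical(got$labels > 0, ref > 0)
    expect_identical(sort(got$table$size),
                     sort(as.integer(table(ref[ref > 0]))))
    # scan-order labelling makes the match exact, not just up to permutation
    expect_identical(sum(got$table$size), sum(sp))
    for (lab in unique(as.vector(ref[ref > 0]))) {
      gl <- got$labels[ref == lab]
      expect_identical(length(unique(gl)), 1L)
    }
  }
})

test_that("minimum-region-size filtering keeps equality, surfaces, and is
           idempotent", {
  # components of sizes 5, 700, 3000
  m <- array(0L, c(40, 40, 40))
  m[1, 1, 1:5] <- 1L                 # size 5
  m[10:16, 10:19, 10:19] <- 1L       # 7*10*10 = 700
  m[25:39, 1:10, 21:40] <- 1L        # 15*10*20 = 3000
  out <- remove_small_regions(m, 700)
  sizes <- sort(label_regions(out)$table$size)
  expect_identical(sizes, c(700L, 3000L))
  # surviving voxel sets are untouched
  expect_identical(out[10:16, 10:19, 10:19], m[10:16, 10:19, 10:19])
  expect_identical(remove_small_regions(m, 0), m)
  expect_identical(remove_small_regions(out, 700), out)
  # agreement with the oracle decomposition on a sparse seeded mask
  set.seed(14)
  sp <- array((runif(16^3) < 0.1) + 0L, c(16, 16, 16))
  ref <- oracle_label3d(sp, 26L)
  keep <- as.integer(names(which(table(ref[ref > 0]) >= 4)))
  expect_identical(remove_small_regions(sp, 4),
                   array((ref %in% keep) + 0L, dim(sp)))
})

test_that("erosion/dilation satisfy duality and convex-solid closing", {
  single <- array(0L, c(7, 7, 7)); single[4, 4, 4] <- 1L
  expect_identical(sum(erode(single, 1)), 0L)

  cube <- array(0L, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- 1L
  expect_identical(erode(dilate(cube, 1), 1), cube)

  set.seed(15)
  m <- array((runif(12^3) < 0.3) + 0L, c(12, 12, 12))
  expect_identical(erode(1L - m, 1), 1L - dilate(m, 1))
  expect_identical(erode(1L - m, 2), 1L - dilate(m, 2))
  expect_error(erode(m, 0), "radius")
})

test_that("morphology schemes behave as designed on micro-fixtures", {
  # isolated voxels removed, one-voxel holes in thick walls filled
  m <- array(0L, c(16, 16, 16))
  m[3:13, 3:13, 3:8] <- 1L     # thick slab
  m[8, 8, 5] <- 0L             # interior hole
  m[15, 15, 15] <- 1L          # isolated speck
  oc <- scheme_open_close(m)
  expect_identical(oc[15, 15, 15], 0L)
  expect_identical(oc[8, 8, 5], 1L)

  # solid cube: interiors preserved, nothing added, only corners/edges of
  # the surface may be rounded by the cross element
  cube <- array(0L, c(16, 16, 16)); cube[4:13, 4:13, 4:13] <- 1L
  oc2 <- scheme_open_close(cube)
  expect_true(all(oc2 <= cube))
  expect_true(all(oc2[5:12, 5:12, 5:12] == 1L))
  co <- scheme_close_open_open2(cube)
  expect_true(all(co <= cube))
  expect_true(all(co[7:10, 7:10, 7:10] == 1L))

  # one-voxel-thick sheet: removed by the radius-2 opening
  sheet <- array(0L, c(16, 16, 16)); sheet[8, 3:14, 3:14] <- 1L
  expect_identical(sum(scheme_close_open_open2(sheet)), 0L)
  expect_identical(sum(scheme_close_open_open2(array(0L, c(6, 6, 6)))), 0L)

  # idempotence of the composite on its own output
  set.seed(16)
  r <- array((runif(14^3) < 0.25) + 0L, c(14, 14, 14))
  once <- scheme_open_close(r)
  expect_identical(scheme_open_close(once), once)
})

test_that("denoiser comparison reports Dice, noise removed and truth lost", {
  truth <- array(0L, c(20, 20, 20)); truth[5:15, 5:15, 5:15] <- 1L
  perfect <- compare_denoisers(truth, truth)
  # region filtering returns a perfect mask untouched; the morphology
  # schemes round its corners even though there is no noise at all
  expect_identical(perfect$dice[perfect$method == "regions"], 1)
  expect_true(all(perfect$dice[perfect$method != "regions"] < 1))
  empty <- array(0L, c(20, 20, 20))
  expect_identical(compare_denoisers(empty, truth)$dice, rep(0, 3))

  # salt noise clear of the truth: region filtering removes exactly it
  set.seed(17)
  noisy <- truth
  clear <- dilate(truth, 2) == 0L
  salt <- which(clear & runif(length(truth)) < 0.002)
  noisy[salt] <- 1L
  rep <- compare_denoisers(noisy, truth, min_size = 50)
  reg <- rep[rep$method == "regions", ]
  expect_identical(reg$true_lost, 0L)
  expect_identical(reg$fp_removed, length(salt))
  expect_identical(reg$dice, 1)
})
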