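test_that("grid planning is ceiling division with deterministic enumeration", {
  g1 <- plan_grid(c(1200, 1600, 1600), block_edge = 256)
  expect_identical(g1$counts, c(5L, 7L, 7L))
  expect_identical(g1$n_blocks, 245L)

  g2 <- plan_grid(c(500, 1497, 1374), block_edge = 256, halo = 16)
  expect_identical(g2$counts, c(2L, 6L, 6L))
  expect_identical(g2$n_blocks, 72L)

  g3 <- plan_grid(c(10, 10, 10), block_edge = 10)
  expect_identical(g3$n_blocks, 1L)
  ref <- block_ref(g3, c(0, 0, 0))
  expect_identical(unname(ref$core[, 2] - ref$core[, 1]), c(10L, 10L, 10L))

  idx <- tubuseg:::block_indices(plan_grid(c(4, 4, 4), 2))
  expect_identical(idx[1:2, "k"], c(0L, 1L))  # x index fastest
  expect_identical(idx[nrow(idx), ], c(i = 1L, j = 1L, k = 1L))

  expect_error(plan_grid(c(0, 4, 4), 2), "positive")
  expect_error(plan_grid(c(4, 4, 4), 0), "positive")
  expect_error(plan_grid(c(4, 4, 4), 2, -1), "non-negative")
})

test_that("every voxel belongs to exactly one core block", {
  for (case in list(c(5, 5, 5, 2), c(17, 9, 23, 7), c(8, 8, 8, 8))) {
    g <- plan_grid(case[1:3], case[4])
    cover <- array(0L, case[1:3])
    idx <- tubuseg:::block_indices(g)
    for (r in seq_len(nrow(idx))) {
      co <- block_ref(g, idx[r, ])$core
      cover[(co[1, 1] + 1):co[1, 2], (co[2, 1] + 1):co[2, 2],
            (co[3, 1] + 1):co[3, 2]] <-
        cover[(co[1, 1] + 1):co[1, 2], (co[2, 1] + 1):co[2, 2],
              (co[3, 1] + 1):co[3, 2]] + 1L
    }
    expect_true(all(cover == 1L))
  }
})

test_that("split -> assemble round trip is bit-exact", {
  v <- rand_volume(c(64, 64, 64), seed = 7)
  st <- split_volume(v, withr::local_tempdir(), block_edge = 20, halo = 0)
  expect_identical(st$meta$block_count, 64L)
  expect_identical(length(list.files(st$path, pattern = "^block_.*tif$")), 64L)
  expect_identical(assemble_volume(st)$data, v$data + 0)

  # odd shape, tiny edge: 27 blocks with edge shapes {2,1}
  v2 <- rand_volume(c(5, 5, 5), seed = 8)
  st2 <- split_volume(v2, withr::local_tempdir(), block_edge = 2)
  expect_identical(st2$meta$block_count, 27L)
  shapes <- dim(read_block(st2, c(2, 2, 2)))
  expect_identical(unname(shapes), c(1L, 1L, 1L))
  expect_identical(dim(assemble_volume(st2)$data), c(5L, 5L, 5L))
  expect_identical(assemble_volume(st2)$data, v2$data + 0)

  # constant zero volume, single block
  v3 <- ct_volume(array(0, c(8, 8, 8)), dtype_bits = 8L)
  st3 <- split_volume(v3, withr::local_tempdir(), block_edge = 8)
  expect_identical(st3$meta$block_count, 1L)
  expect_true(all(assemble_volume(st3)$data == 0))
})

test_that("round trip holds over randomized shapes, edges and bit depths", {
  set.seed(42)
  for (case in 1:12) {
    dims <- sample(3:18, 3, replace = TRUE)
    edge <- sample(1:10, 1)
    bits <- sample(c(8L, 16L, 32L), 1)
    v <- rand_volume(dims, bits = bits, seed = 100 + case)
    st <- split_volume(v, withr::local_tempdir(), block_edge = edge)
    expect_identical(assemble_volume(st)$data, v$data + 0)
  }
})

test_that("store refuses overwrite and reports missing blocks by index", {
  v <- rand_volume(c(6, 6, 6), seed = 1)
  path <- withr::local_tempdir()
  st <- split_volume(v, path, block_edge = 3)
  expect_error(split_volume(v, path, block_edge = 3), "already exists")
  expect_s3_class(split_volume(v, path, block_edge = 3, overwrite = TRUE),
                  "block_store")
  unlink(file.path(path, "block_0001_0000_0001.tif"))
  expect_error(assemble_volume(load_block_store(path)), "1,0,1")
})

test_that("halo reads match direct windows and mirror at volume faces", {
  v <- rand_volume(c(64, 64, 64), seed = 3)
  st <- split_volume(v, withr::local_tempdir(), block_edge = 20, halo = 4)

  # halo 0: the core block itself
  expect_identical(read_block_with_halo(st, c(1, 1, 1), 0),
                   v$data[21:40, 21:40, 21:40] + 0)
  # interior block: equals the directly-sliced window
  expect_identical(read_block_with_halo(st, c(1, 1, 1), 4),
                   v$data[17:44, 17:44, 17:44] + 0)
  # corner block: out-of-volume planes are mirrored in-volume planes
  w <- read_block_with_halo(st, c(0, 0, 0), 2)
  expect_identical(unname(w[1, 3:12, 3:12]), unname(v$data[2, 1:10, 1:10] + 0))
  expect_identical(unname(w[3:12, 1, 3:12]), unname(v$data[1:10, 2, 1:10] + 0))
  expect_error(read_block_with_halo(st, c(0, 0, 0), 21), "halo")
  expect_error(read_block_with_halo(st, c(9, 0, 0), 2), "outside")
})

test_that("blockwise filtering equals whole-volume filtering when the halo
           covers the footprint", {
  v <- rand_volume(c(48, 48, 48), seed = 5)
  st <- split_volume(v, withr::local_tempdir(), block_edge = 16, halo = 16)

  # identity operator: output store equals input
  idem <- map_blocks(st, identity, withr::local_tempdir(), halo = 0)
  expect_identical(assemble_volume(idem)$data, v$data + 0)

  # integer box-sum, radius 3, halo 8: exact equality
  op <- function(b) box_filter3(b, 3, normalise = FALSE)
  out <- map_blocks(st, op, withr::local_tempdir(), halo = 8, out_bits = 32L)
  expect_identical(assemble_volume(out)$data, box_filter3(v$data + 0, 3, FALSE))

  # order independence: permuted block order gives the identical store
  set.seed(9)
  idx <- tubuseg:::block_indices(tubuseg:::store_grid(st))
  out2 <- map_blocks(st, op, withr::local_tempdir(), halo = 8,
                     out_bits = 32L, indices = idx[sample(nrow(idx)), ])
  expect_identical(assemble_volume(out2)$data, assemble_volume(out)$data)

  # halo 0: seams appear (this is what halos are for)
  out0 <- map_blocks(st, op, withr::local_tempdir(), halo = 0, out_bits = 32L)
  expect_gt(max(abs(assemble_volume(out0)$data -
                    box_filter3(v$data + 0, 3, FALSE))), 0)

  # shape-changing operator violates the contract
  expect_error(map_blocks(st, function(b) b[-1, , , drop = FALSE],
                          withr::local_tempdir(), halo = 0),
               "contract violation")
})

test_that("aggregated metadata equals whole-volume statistics", {
  # constant volume: min = max, a single occupied bin
  vc <- ct_volume(array(42, c(6, 6, 6)), dtype_bits = 8L)
  stc <- split_volume(vc, withr::local_tempdir(), block_edge = 4)
  stc <- compute_meta(stc)
  expect_identical(stc$meta$global_min, 42)
  expect_identical(stc$meta$global_max, 42)
  expect_identical(sum(stc$meta$histogram$counts > 0), 1L)

  v <- rand_volume(c(20, 20, 20), seed = 11)
  st <- split_volume(v, withr::local_tempdir(), block_edge = 7)
  st <- compute_meta(st)
  expect_identical(st$meta$global_min, min(v$data) + 0)
  expect_identical(st$meta$global_max, max(v$data) + 0)
  expect_identical(sum(st$meta$histogram$counts), 8000L)
  # identical to the unsplit-volume histogram
  ref <- tubuseg:::hist_counts(v$data, min(v$data), max(v$data), 256L)
  expect_identical(st$meta$histogram$counts, ref)
})
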