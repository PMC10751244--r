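# Block cropping and per-block segmentation into labelled fragments.

test_that("crop_blocks tiles the field exactly once", {
  img <- calibrated_image(matrix(runif(1000 * 1000), 1000, 1000), 0.1)
  blocks <- crop_blocks(img, 20)
  expect_length(blocks, 25L) # 100x100 um in 5x5 blocks of 20 um
  expect_true(all(vapply(blocks, function(b) all(dim(b$pixels) == c(200, 200)),
                         logical(1))))

  img2 <- calibrated_image(matrix(0, 500, 500), 0.1) # 50x50 um
  blocks2 <- crop_blocks(img2, 20)
  expect_length(blocks2, 9L) # ceiling tiling, edge blocks 10 um
  expect_equal(dim(blocks2[[9]]$pixels), c(100, 100))

  # reassembly is bit-exact
  rec <- matrix(NA_real_, 1000, 1000)
  for (b in blocks) {
    rs <- b$origin_px[["row"]] + seq_len(nrow(b$pixels)) - 1L
    cs <- b$origin_px[["col"]] + seq_len(ncol(b$pixels)) - 1L
    rec[rs, cs] <- b$pixels
  }
  expect_identical(rec, unclass(img), ignore_attr = TRUE)

  expect_error(crop_blocks(matrix(0, 10, 10)), "calibration")
})

test_that("noiseless scenes are segmented exactly; blank blocks give nothing", {
  # one 20x20-um cell = one block; bars recovered pixel-for-pixel
  sq <- generate_cell_mosaic(1, c(20, 20))
  gt <- place_fragments(sq, fragment_mix("bar", 8, 2, 0, 0.5), seed = 4,
                        field_size_um = c(20, 20))
  spec <- scene_spec(field_size_um = c(20, 20), n_cells = 1,
                     mix = fragment_mix("bar", 8, 2), blur_sigma_um = 0,
                     noise_sd = 0, seed = 4)
  img <- render(spec, gt)
  seg <- segment_fov(img)
  expect_equal(nrow(seg$table), 8L)
  for (id in gt$fragments$id) {
    tm <- unclass(gt$labels) == id
    expect_equal(best_jaccard(tm, unclass(seg$labels)), 1)
  }

  blank <- crop_blocks(calibrated_image(matrix(0.2, 100, 100), 0.1))[[1]]
  expect_equal(nrow(segment_fragments(blank)$table), 0L)

  # pure noise block: dynamic range below epsilon -> no fragments, no error
  noisy <- crop_blocks(calibrated_image(
    matrix(0.1 + rnorm(1e4, 0, 0.04), 100, 100), 0.1))[[1]]
  expect_equal(nrow(segment_fragments(noisy)$table), 0L)
})

test_that("segmentation is idempotent and monotone in min_area", {
  spec <- small_scene_spec(seed = 21)
  sc <- simulate_scene(spec)
  b <- crop_blocks(sc$image)[[2]]
  s1 <- segment_fragments(b)
  s2 <- segment_fragments(b)
  expect_identical(s1$labels, s2$labels)
  counts <- vapply(c(1L, 3L, 10L, 30L), function(ma)
    nrow(segment_fragments(b, segment_config(min_area_px = ma))$table),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("vectorized labelling matches brute-force flood fill", {
  set.seed(42)
  for (rep in 1:10) {
    mask <- matrix(runif(1600) < 0.35, 40, 40)
    a <- junctmorph:::label_components(mask, 8L)
    b <- junctmorph:::flood_fill_label(mask, 8L)
    # same partition up to label permutation
    expect_equal(max(a), max(b))
    key <- paste(a[mask], b[mask])
    expect_equal(length(unique(key)), max(a))
  }
})

test_that("merged tables have unique ids and flag block-border objects", {
  spec <- small_scene_spec(seed = 8)
  sc <- simulate_scene(spec)
  seg <- segment_fov(sc$image)
  expect_equal(seg$table$id, seq_len(nrow(seg$table)))

  # a bar crossing the x = 20 um block boundary is split into two flagged rows
  img <- matrix(0, 200, 400) # 20 x 40 um
  img[100:104, 150:250] <- 1
  seg2 <- segment_fov(calibrated_image(img, 0.1))
  expect_equal(nrow(seg2$table), 2L)
  expect_true(all(seg2$table$border))

  # empty FOV
  seg3 <- segment_fov(calibrated_image(matrix(0, 100, 100), 0.1))
  expect_equal(nrow(seg3$table), 0L)
})

test_that("noisy, blurred scenes are recovered at high fidelity", {
  spec <- small_scene_spec(seed = 31, noise_sd = 0.05, blur_sigma_um = 0.2)
  sc <- simulate_scene(spec)
  seg <- segment_fov(sc$image)
  truth_ids <- sc$truth$fragments$id
  jac <- vapply(truth_ids, function(id)
    recovery_jaccard(unclass(sc$truth$labels) == id, unclass(seg$labels)),
    numeric(1))
  expect_gte(mean(jac >= 0.7), 0.95)
})
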