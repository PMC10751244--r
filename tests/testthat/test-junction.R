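# Zippering metrics: perimeter assignment, coverage, density, length CDF.

square40 <- function() rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40), c(0, 0))

test_that("perimeter assignment recovers generator junctional flags", {
  polys <- generate_cell_mosaic(1, c(40, 40))
  gt <- place_fragments(polys, rbind(fragment_mix("bar", 10, 3, 0, 0.5),
                                     fragment_mix("punctum", 5, 1)),
                        seed = 9, field_size_um = c(40, 40))
  frags <- data.frame(id = gt$fragments$id,
                      centroid_x_um = gt$fragments$x_um,
                      centroid_y_um = gt$fragments$y_um,
                      length_um = gt$fragments$length_um)
  ann <- assign_fragments_to_perimeter(frags, polys[[1]], tolerance_um = 0.5)
  expect_setequal(ann$fragments$id, gt$fragments$id[gt$fragments$junctional])
  expect_equal(ann$n_pan_cellular, 5L)

  # interior fragment at 5 um from the perimeter is pan-cellular at 1 um
  inner <- data.frame(id = 1L, centroid_x_um = 20, centroid_y_um = 5,
                      length_um = 2)
  ann2 <- assign_fragments_to_perimeter(inner, square40(), tolerance_um = 1)
  expect_equal(nrow(ann2$fragments), 0L)

  # tolerance monotonicity
  n_at <- vapply(c(0.5, 1, 2, 6), function(tol)
    nrow(assign_fragments_to_perimeter(frags, polys[[1]], tol)$fragments),
    integer(1))
  expect_true(all(diff(n_at) >= 0))

  open_poly <- rbind(c(0, 0), c(40, 0), c(40, 40))
  expect_error(assign_fragments_to_perimeter(frags, open_poly), "closed")
})

test_that("coverage is summed length over perimeter times 100", {
  # perimeter 160 um; lengths 16 + 16 + 32 = 64 -> 40%
  frags <- data.frame(id = 1:3, centroid_x_um = c(20, 0.2, 39.9),
                      centroid_y_um = c(0.1, 20, 30),
                      length_um = c(16, 16, 32),
                      length_skeleton_um = c(16, 16, 32))
  ann <- assign_fragments_to_perimeter(frags, square40(), 1)
  expect_equal(as.numeric(coverage_percent(ann)), 40)
  expect_false(attr(coverage_percent(ann), "overlap_flag"))

  # no fragments -> 0%
  ann0 <- assign_fragments_to_perimeter(frags[0, ], square40(), 1)
  expect_equal(as.numeric(coverage_percent(ann0)), 0)

  # splitting a fragment into abutting halves conserves coverage
  split <- data.frame(id = 1:4, centroid_x_um = c(20, 0.2, 39.9, 39.9),
                      centroid_y_um = c(0.1, 20, 28, 34),
                      length_um = c(16, 16, 16, 16),
                      length_skeleton_um = c(16, 16, 16, 16))
  ann_s <- assign_fragments_to_perimeter(split, square40(), 1)
  expect_equal(as.numeric(coverage_percent(ann_s)), 40)

  # summed length beyond the perimeter raises the overlap flag
  over <- data.frame(id = 1, centroid_x_um = 20, centroid_y_um = 0.1,
                     length_um = 170, length_skeleton_um = 170)
  ann_o <- assign_fragments_to_perimeter(over, square40(), 1)
  expect_true(attr(coverage_percent(ann_o), "overlap_flag"))
})

test_that("fragment density normalizes to 100 um of vessel", {
  expect_equal(fragments_per_100um(5, 50), 10)
  expect_equal(fragments_per_100um(0, 80), 0)
  expect_equal(fragments_per_100um(7, 200), fragments_per_100um(7, 100) / 2)
  expect_error(fragments_per_100um(3, 0), "> 0")
})

test_that("cumulative length frequency is a right-continuous CDF", {
  cdf <- cumulative_length_frequency(c(1, 2, 3))
  expect_equal(cdf$cumulative_fraction[cdf$length_um == 2], 2 / 3)
  expect_equal(max(cdf$cumulative_fraction), 1)
  f <- attr(cdf, "ecdf")
  expect_equal(f(2.5), 2 / 3) # right-continuous step
  expect_error(cumulative_length_frequency(numeric(0)), "no lengths")

  # stochastic dominance: longer population lies at or below everywhere
  set.seed(11)
  short <- rgamma(300, shape = 4, rate = 2)
  long <- short + 1.5
  fs <- attr(cumulative_length_frequency(short), "ecdf")
  fl <- attr(cumulative_length_frequency(long), "ecdf")
  grid <- seq(0, max(long), length.out = 200)
  expect_true(all(fl(grid) <= fs(grid) + 1e-12))
})

test_that("per-cell junction metrics assign each fragment to one nearest cell", {
  sc <- simulate_scene(small_scene_spec(seed = 13, noise_sd = 0,
                                        blur_sigma_um = 0))
  seg <- segment_fov(sc$image)
  sh <- shape_table(seg)
  jm <- junction_metrics(sh, sc$truth$cell_polygons, tolerance_um = 1)
  expect_equal(nrow(jm), 4L)
  expect_true(all(jm$coverage_pct >= 0))
  # every junctional truth fragment is counted exactly once across cells
  expect_lte(sum(jm$n_fragments),
             nrow(sh)) # no double assignment
  expect_gte(sum(jm$n_fragments),
             sum(sc$truth$fragments$junctional) * 0.9)
})
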