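# Scene generator: mosaics, fragment placement, rendering, clearance series.

test_that("cell mosaic tiles the field and is seed-reproducible", {
  # one cell: the whole field
  one <- generate_cell_mosaic(1, c(100, 100), seed = 7)
  expect_length(one, 1L)
  expect_equal(poly_area(one[[1]]), 100 * 100)

  polys <- generate_cell_mosaic(25, c(100, 100), seed = 7)
  expect_length(polys, 25L)
  # conservation: Voronoi cells clipped to the field partition its area
  expect_equal(sum(vapply(polys, poly_area, numeric(1))), 100 * 100,
               tolerance = 1e-8)
  # every polygon is closed
  for (p in polys) expect_equal(p[1, ], p[nrow(p), ])
  expect_identical(polys, generate_cell_mosaic(25, c(100, 100), seed = 7))
  expect_error(generate_cell_mosaic(0, c(100, 100)), "n_cells")
})

test_that("fragment placement records truth and respects perimeter capacity", {
  sq <- generate_cell_mosaic(1, c(40, 40))
  gt <- place_fragments(sq, fragment_mix("bar", 10, 5, 0, 0.5), seed = 2,
                        field_size_um = c(40, 40))
  expect_equal(nrow(gt$fragments), 10L)
  expect_true(all(gt$fragments$length_um == 5))
  expect_true(all(gt$fragments$true_class == "bar"))
  # every labeled pixel belongs to exactly one recorded fragment
  expect_setequal(setdiff(unique(as.integer(gt$labels)), 0L), gt$fragments$id)
  # junctional fragments lie on the perimeter band
  d <- dist_to_polyline(cbind(gt$fragments$x_um, gt$fragments$y_um), sq[[1]])
  expect_true(all(d <= 0.5))
  # label image object count equals the record count (noiseless, no merging)
  lab <- unclass(gt$labels)
  expect_equal(max(junctmorph:::label_components(lab > 0)), 10L)

  # empty mix
  gt0 <- place_fragments(sq, fragment_mix("bar", 0, 5), seed = 1,
                         field_size_um = c(40, 40))
  expect_equal(nrow(gt0$fragments), 0L)
  expect_true(all(gt0$labels == 0L))

  # overload: 40 bars of 5 um on a 160-um perimeter cannot fit
  expect_error(place_fragments(sq, fragment_mix("bar", 40, 5), seed = 1,
                               field_size_um = c(40, 40)),
               "exceeds perimeter")
})

test_that("near-full perimeter packing conserves arc length", {
  sq <- generate_cell_mosaic(1, c(40, 40))
  perim <- poly_perimeter(sq[[1]]) # independent polyline-length oracle: 160
  expect_equal(perim, 160)
  # 7 bars of 5 um fit per 40-um edge at gap 0.1: 28 in total
  gt <- place_fragments(sq, fragment_mix("bar", 28, 5, 0, 0.5), seed = 3,
                        field_size_um = c(40, 40), min_gap_um = 0.1)
  # summed lengths fill the perimeter up to one fragment (+ gaps) per edge
  expect_lt(perim - sum(gt$fragments$length_um), 4 * (5 + 0.2) + 28 * 0.1)
  # fragments stay on the perimeter and respect spacing: all pairwise
  # center distances exceed the smaller of the two half-length sums
  d <- as.matrix(dist(cbind(gt$fragments$x_um, gt$fragments$y_um)))
  diag(d) <- Inf
  expect_true(all(d > 0.5)) # no coincident placements
})

test_that("rendering is exact without noise/blur, seeded, and unbiased in noise", {
  spec <- scene_spec(field_size_um = c(20, 20), n_cells = 1,
                     mix = fragment_mix("bar", 5, 3, 0, 0.5, intensity = 2),
                     blur_sigma_um = 0, noise_sd = 0, background = 0.25,
                     seed = 11)
  sc <- simulate_scene(spec)
  expected <- matrix(0.25, 200, 200)
  expected[unclass(sc$truth$labels) > 0] <- 2.25
  expect_equal(unclass(sc$image), expected, ignore_attr = TRUE)

  # seeded determinism of the noisy render
  spec2 <- scene_spec(field_size_um = c(20, 20), n_cells = 1,
                      mix = fragment_mix("bar", 5, 3), seed = 11)
  expect_identical(render(spec2, sc$truth), render(spec2, sc$truth))

  # Monte-Carlo: noise averages to zero
  tr <- place_fragments(generate_cell_mosaic(1, c(10, 10)),
                        fragment_mix("bar", 2, 3), seed = 5,
                        field_size_um = c(10, 10))
  # background at 6 sigma so the >= 0 clip does not bias the comparison
  clean <- render(scene_spec(field_size_um = c(10, 10), n_cells = 1,
                             mix = fragment_mix("bar", 2, 3),
                             noise_sd = 0, background = 0.3, seed = 1), tr)
  devs <- vapply(1:200, function(s) {
    sp <- scene_spec(field_size_um = c(10, 10), n_cells = 1,
                     mix = fragment_mix("bar", 2, 3), noise_sd = 0.05,
                     background = 0.3, seed = s)
    mean(render(sp, tr) - clean)
  }, numeric(1))
  expect_lt(abs(mean(devs)), 3 * 0.05 / sqrt(10000 * 200) + 2e-5)
})

test_that("clearance series follows baseline + I0 exp(-kt) + noise", {
  s <- generate_clearance_series(k_true = log(2), I0 = 1, baseline = 0,
                                 noise_sd = 0)
  expect_equal(s$intensity[s$time_h == 1], 0.5)
  expect_true(s$is_baseline[1])

  s0 <- generate_clearance_series(k_true = 0.3, I0 = 2, baseline = 0.5,
                                  noise_sd = 0, timepoints_h = c(1e-12, 1, 2))
  expect_equal(s0$intensity[2], 2.5, tolerance = 1e-9) # t -> 0: baseline + I0

  s2 <- generate_clearance_series(k_true = 0.5, I0 = 3, baseline = 0,
                                  noise_sd = 0)
  expect_equal(s2$intensity[s2$time_h == 2], 3 * exp(-1), tolerance = 1e-12)

  expect_identical(generate_clearance_series(0.5, noise_sd = 0.1, seed = 4),
                   generate_clearance_series(0.5, noise_sd = 0.1, seed = 4))
  expect_error(generate_clearance_series(0.5, timepoints_h = c(2, 1)))
})
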