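# Quartile-binned four-category classifier and per-FOV percentages.

test_that("quartile boundaries use linear-interpolation quantiles", {
  q <- compute_quartiles(1:8)
  expect_equal(c(q$q1, q$q2, q$q3), c(2.75, 4.5, 6.25))
  expect_equal(q$n, 8L)

  qc <- compute_quartiles(rep(3.2, 10))
  expect_equal(c(qc$q1, qc$q2, qc$q3), rep(3.2, 3))

  set.seed(1)
  for (i in 1:20) {
    q <- compute_quartiles(rlnorm(sample(4:50, 1)))
    expect_true(q$q1 <= q$q2 && q$q2 <= q$q3)
  }
  expect_error(compute_quartiles(c(1, 2, 3)), "insufficient")
})

test_that("fragments classify by the category-1..4 joint binning rule", {
  q <- compute_quartiles(c(1, 2, 3, 4, 5, 6, 7, 8)) # Q1 2.75, Q2 4.5, Q3 6.25
  # round, low-AR fragment -> category 4
  expect_equal(classify_fragment(0.9, 1.5, q), 4L)
  # elongated, high-AR fragment -> category 1
  expect_equal(classify_fragment(0.1, 7.5, q), 1L)
  # discordant joint bin: circularity says 4, AR says 2
  sh <- classify_fragments(data.frame(circularity = 0.9, aspect_ratio = 5),
                           q, "lenient")
  expect_equal(sh$category, 4L)
  expect_true(sh$discordant)
  sh2 <- classify_fragments(data.frame(circularity = 0.9, aspect_ratio = 5),
                            q, "strict")
  expect_true(is.na(sh2$category))

  # bin-edge conventions
  expect_equal(classify_fragment(0, 9, q), 1L)      # circ 0 -> bin 1
  expect_equal(classify_fragment(0.25, 9, q), 1L)   # right-closed circ bins
  expect_equal(classify_fragment(0.2500001, 9, q), 2L)
  edge <- classify_fragments(
    data.frame(circularity = c(0.9, 0.4), aspect_ratio = c(2.75, 6.25)), q)
  expect_equal(edge$ar_bin, c(4L, 2L)) # boundary ties fall in the lower-AR bin

  expect_error(classify_fragments(
    data.frame(circularity = 1.2, aspect_ratio = 2), q), "circularity")
})

test_that("FOV percentages are computed on the total fragment count", {
  p <- fov_percentages(c(4, 4, 3, 2))
  expect_equal(c(p$pct_cat4, p$pct_cat3, p$pct_cat2, p$pct_cat1),
               c(50, 25, 25, 0))
  p1 <- fov_percentages(rep(1L, 7))
  expect_equal(p1$pct_cat1, 100)
  expect_error(fov_percentages(integer(0)), "undefined|no classified")

  # strict mode: unclassified included in the total, everything sums to 100
  p2 <- fov_percentages(c(1, 2, NA, NA, 3))
  expect_equal(p2$pct_cat1 + p2$pct_cat2 + p2$pct_cat3 + p2$pct_cat4 +
                 p2$pct_unclassified, 100)
  expect_equal(p2$pct_unclassified, 40)

  # uniform draw: ~25% each within binomial error
  set.seed(7)
  u <- sample(1:4, 1000, replace = TRUE)
  pu <- fov_percentages(u)
  for (k in 1:4) {
    expect_equal(pu[[paste0("pct_cat", k)]], 25,
                 tolerance = 3 * 100 * sqrt(0.25 * 0.75 / 1000) / 25)
  }
})

test_that("aspect-ratio bins each hold a quarter of the reference population", {
  set.seed(3)
  ar <- rlnorm(101, 1, 0.6) # no ties almost surely
  sh <- classify_fragments(
    data.frame(circularity = runif(101), aspect_ratio = ar),
    compute_quartiles(ar))
  counts <- table(sh$ar_bin)
  expect_true(all(abs(counts - 101 / 4) <= 1 + 1e-9))
})

test_that("cohort comparison delegates to the one-tailed rank-sum test", {
  # A below B; alternative 'B greater' is alternative = 'less' for group A
  r <- cohort_compare(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$p_value, 1 / 20)
  # identical groups: no shift
  r2 <- cohort_compare(c(5, 6, 7), c(5, 6, 7), alternative = "less")
  expect_gte(r2$p_value, 0.5)
  # swapping groups reverses one-tailed significance
  r3 <- cohort_compare(c(4, 5, 6), c(1, 2, 3), alternative = "less")
  expect_equal(r3$p_value, 1)
})

test_that("animal-level aggregation averages FOV percentages within animal", {
  fovs <- rbind(fov_percentages(c(4, 4, 1, 1), fov = 1),
                fov_percentages(c(4, 4, 4, 4), fov = 2),
                fov_percentages(c(1, 1, 1, 1), fov = 3))
  am <- animal_means(fovs, animal = c("m1", "m1", "m2"))
  expect_equal(am$pct_cat4[am$animal == "m1"], (50 + 100) / 2)
  expect_equal(am$pct_cat4[am$animal == "m2"], 0)
})
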