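test_that("annual deforestation is the year-on-year cover drop", {
  expect_equal(as.vector(annual_deforestation(cover1(c(100, 100, 100)))$value),
               c(0, 0))
  expect_equal(as.vector(annual_deforestation(cover1(c(100, 75)))$value), 25)
  expect_error(annual_deforestation(cover1(100)),
               class = "defoeval_insufficient_series")
})

test_that("deforestation telescopes to the total cover change", {
  cov <- random_cover(7, 5, 9, seed = 42)
  defo <- annual_deforestation(cov)
  total <- apply(defo$value, c(1, 2), sum)
  expect_equal(total, cov$cover[, , 1] - cov$cover[, , 9], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("regrowth triggers strict error or lenient clipping", {
  bad <- forest_cover_series(array(c(50, 60), c(1, 1, 2)), 2000:2001, 90,
                             check = FALSE)
  expect_error(annual_deforestation(bad, "strict"),
               class = "defoeval_monotonicity_error")
  expect_warning(lenient <- annual_deforestation(bad, "lenient"), "regrowth")
  expect_equal(as.vector(lenient$value), 0)
  expect_error(forest_cover_series(array(c(50, 60), c(1, 1, 2)), 2000:2001, 90),
               class = "defoeval_monotonicity_error")
})

test_that("block aggregation matches hand values and the brute-force oracle", {
  m <- matrix(100, 3, 3)
  cov <- forest_cover_series(array(m, c(3, 3, 1)), 2000, 30)
  expect_equal(as.vector(aggregate_cover(cov, 3)$cover), 100)

  m2 <- matrix(0, 3, 3); m2[c(1, 5, 9)] <- 100
  cov2 <- forest_cover_series(array(m2, c(3, 3, 1)), 2000, 30)
  expect_equal(as.vector(aggregate_cover(cov2, 3)$cover), 100 * 3 / 9,
               tolerance = 1e-12)

  set.seed(3)
  m3 <- matrix(100 * rbinom(54 * 36, 1, 0.6), 54, 36)
  cov3 <- forest_cover_series(array(m3, c(54, 36, 1)), 2000, 30)
  expect_equal(aggregate_cover(cov3, 9)$cover[, , 1], bf_block_mean(m3, 9),
               tolerance = 1e-12)
  # 30 -> 270 directly equals 30 -> 90 -> 270
  expect_equal(aggregate_cover(cov3, 9)$cover,
               aggregate_cover(aggregate_cover(cov3, 3), 3)$cover,
               tolerance = 1e-10)
  expect_equal(aggregate_cover(aggregate_cover(cov3, 3), 3)$resolution, 270)
})

test_that("total forest area is conserved across resolutions", {
  cov <- random_cover(54, 36, 3, resolution = 30, seed = 9)
  a30 <- forest_area_ha(cov, 2002)
  a90 <- forest_area_ha(aggregate_cover(cov, 3), 2002)
  a270 <- forest_area_ha(aggregate_cover(cov, 9), 2002)
  expect_equal(a90 / a30, 1, tolerance = 1e-10)
  expect_equal(a270 / a30, 1, tolerance = 1e-10)
})

test_that("differencing commutes with block aggregation", {
  cov <- random_cover(27, 18, 4, resolution = 30, seed = 5)
  d_then_a <- vapply(1:3, function(k)
    defoeval:::block_mean(annual_deforestation(cov)$value[, , k], 3),
    matrix(0, 9, 6))
  a_then_d <- annual_deforestation(aggregate_cover(cov, 3))$value
  expect_equal(unname(a_then_d), unname(d_then_a), tolerance = 1e-10)
})

test_that("edge distance matches the all-pairs oracle and conventions", {
  m <- matrix(100, 3, 3); m[1, 1] <- 0
  cov <- forest_cover_series(array(m, c(3, 3, 1)), 2005, 90)
  d <- distance_to_forest_edge(cov, 2005)
  expect_equal(d[1, 2], 90)       # orthogonal neighbor of a clearing
  expect_equal(d[1, 1], 0)        # non-forest convention
  expect_equal(d[2, 2], 90 * sqrt(2))

  set.seed(7)
  mask <- matrix(100 * rbinom(400, 1, 0.7), 20, 20)
  cov2 <- forest_cover_series(array(mask, c(20, 20, 1)), 2005, 90)
  expect_equal(distance_to_forest_edge(cov2, 2005),
               bf_edge_distance(mask > 0, 90), tolerance = 1e-9)

  full <- forest_cover_series(array(100, c(4, 5, 1)), 2005, 90)
  sentinel <- sqrt((4 * 90)^2 + (5 * 90)^2)
  expect_equal(distance_to_forest_edge(full, 2005),
               matrix(sentinel, 4, 5))
  expect_error(distance_to_forest_edge(full, 1999),
               class = "defoeval_lookup_error")
})

test_that("edge distance is 0 iff non-forest and never exceeds the sentinel", {
  for (s in 1:5) {
    set.seed(s)
    mask <- matrix(100 * rbinom(150, 1, runif(1, 0.2, 0.9)), 15, 10)
    cov <- forest_cover_series(array(mask, c(15, 10, 1)), 2005, 90)
    d <- distance_to_forest_edge(cov, 2005)
    expect_true(all((d == 0) == (mask == 0)))
    expect_true(all(d <= sqrt((15 * 90)^2 + (10 * 90)^2)))
  }
})

test_that("forest decline percentage is basic share arithmetic", {
  expect_equal(forest_decline_pct(100, 80), 20)
  expect_equal(forest_decline_pct(100, 100), 0)
  expect_error(forest_decline_pct(0, 10), class = "defoeval_argument_error")
})
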