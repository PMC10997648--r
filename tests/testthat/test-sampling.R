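baseline_cover <- function(nr = 6, nc = 6, zero_cells = NULL) {
  m <- matrix(80, nr, nc)
  if (!is.null(zero_cells)) m[zero_cells] <- 0
  forest_cover_series(array(rep(m, 2), c(nr, nc, 2)), 2004:2005, 90,
                      check = FALSE)
}

test_that("eligibility applies the cover, overlap and renewal rules", {
  mgmt <- toy_management(6, 6, overlap_cells = cbind(3, 3))
  cov <- baseline_cover(zero_cells = cbind(1, 1))
  cells <- eligible_cells(mgmt, cov, 2005)
  # 36 cells minus the bare cell (1,1) and the overlap cell (3,3)
  expect_equal(nrow(cells), 34)
  expect_false(any(cells$row == 1 & cells$col == 1))   # 0% baseline cover
  expect_false(any(cells$row == 3 & cells$col == 3))   # overlapping claim
  expect_setequal(unique(cells$treatment), c(0, 1))

  # renewed-only on a map with no renewed CFM signals emptiness
  mgmt2 <- toy_management(renewed = FALSE)
  out <- eligible_cells(mgmt2, cov, 2005, kinds = "CFM", renewed_only = TRUE)
  expect_equal(nrow(out), 0)
  expect_true(attr(out, "empty"))

  # units established at/after the baseline year are not yet in scope
  mgmt3 <- toy_management(established = c(2005, 1995))
  expect_equal(unique(eligible_cells(mgmt3, cov, 2005)$kind), "MNP")
})

test_that("sampling everything returns every eligible cell", {
  mgmt <- toy_management()
  cells <- eligible_cells(mgmt, baseline_cover(), 2005)
  out <- spatially_balanced_sample(cells, nrow(cells), seed = 1)
  expect_equal(sort(out$cell_id), sort(cells$cell_id))
})

test_that("quadrant allocation is proportional to eligible-cell counts", {
  # 90% of cells in the north-west quadrant, 10% in the south-east
  cells <- rbind(
    data.frame(cell_id = 1:900, row = rep(1:30, 30),
               col = rep(1:30, each = 30)),
    data.frame(cell_id = 1000 + 1:100, row = 60 + rep(1:10, 10),
               col = 60 + rep(1:10, each = 10)))
  out <- spatially_balanced_sample(cells, 100, seed = 42)
  nw <- sum(out$cell_id <= 900)
  expect_equal(nw, 90)
  expect_equal(nrow(out) - nw, 10)
})

test_that("sampling is reproducible and refuses oversampling", {
  mgmt <- toy_management()
  cells <- eligible_cells(mgmt, baseline_cover(), 2005)
  a <- spatially_balanced_sample(cells, 10, seed = 7)
  b <- spatially_balanced_sample(cells, 10, seed = 7)
  expect_identical(a$cell_id, b$cell_id)
  expect_false(identical(
    a$cell_id, spatially_balanced_sample(cells, 10, seed = 8)$cell_id))
  expect_error(spatially_balanced_sample(cells, nrow(cells) + 1, seed = 1),
               class = "defoeval_sampling_error")
})

test_that("stratified draws track area shares where uniform draws stray", {
  # clustered fixture: four quadrants with very unequal cell counts
  set.seed(99)
  qspec <- list(c(0, 0, 5200), c(0, 60, 2400), c(60, 0, 1600), c(60, 60, 800))
  cells <- do.call(rbind, lapply(seq_along(qspec), function(q) {
    s <- qspec[[q]]
    data.frame(cell_id = q * 100000 + seq_len(s[3]),
               row = s[1] + sample(1:50, s[3], TRUE),
               col = s[2] + sample(1:50, s[3], TRUE), quad = q)
  }))
  cells <- cells[!duplicated(cells[c("row", "col")]), ]
  shares <- as.numeric(table(cells$quad)) / nrow(cells)

  dev_strat <- sapply(1:50, function(s) {
    out <- spatially_balanced_sample(cells, 1000, seed = s)
    max(abs(as.numeric(table(factor(out$quad, 1:4))) / 1000 - shares))
  })
  dev_unif <- sapply(1:50, function(s) {
    set.seed(s)
    out <- cells[sample.int(nrow(cells), 1000), ]
    max(abs(as.numeric(table(factor(out$quad, 1:4))) / 1000 - shares))
  })
  expect_true(all(dev_strat <= 0.03))
  expect_gt(max(dev_unif), 0.03)  # plain uniform misses the +/-3 pp band
  expect_lt(mean(dev_strat), mean(dev_unif))
})
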