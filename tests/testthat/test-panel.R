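make_random_panel <- function(n_cells = 50, n_years = 6, seed = 1,
                              int_weights = FALSE) {
  set.seed(seed)
  cell <- rep(seq_len(n_cells), each = n_years)
  x1 <- rnorm(n_cells * n_years)
  x2 <- rnorm(n_cells * n_years)
  fe <- rnorm(n_cells)[cell]
  y <- 2 * x1 - 1.5 * x2 + fe + rnorm(n_cells * n_years)
  w <- if (int_weights) sample(1:3, n_cells * n_years, TRUE) else
    rep(1, n_cells * n_years)
  list(y = y, X = cbind(x1 = x1, x2 = x2), cell = cell, w = w,
       site = rep(rep(1:10, length.out = n_cells), each = n_years))
}

test_that("within estimator reproduces constructed slopes and absorbs shifts", {
  y <- c(5, 6, 9, 11); x <- c(0, 1, 0, 2); cell <- c("A", "A", "B", "B")
  fit <- fit_fixed_effects_ols(y, cbind(x = x), cell)
  expect_equal(unname(fit$coefficients["x"]), 1, tolerance = 1e-12)

  y2 <- y + c(100, 100, 0, 0)   # constant added to one cell's outcomes
  fit2 <- fit_fixed_effects_ols(y2, cbind(x = x), cell)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
})

test_that("within estimator equals dummy-variable OLS (dense oracle)", {
  p <- make_random_panel(50, 6, seed = 2)
  fit <- fit_fixed_effects_ols(p$y, p$X, p$cell)
  oracle <- bf_dummy_ols(p$y, p$X, p$cell)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-8)

  pw <- make_random_panel(40, 5, seed = 3, int_weights = TRUE)
  fitw <- fit_fixed_effects_ols(pw$y, pw$X, pw$cell, pw$w)
  oraclew <- bf_dummy_ols(pw$y, pw$X, pw$cell, pw$w)
  expect_equal(unname(fitw$coefficients), unname(oraclew), tolerance = 1e-8)
})

test_that("integer-weighted fit equals the row-expanded unweighted fit", {
  p <- make_random_panel(30, 4, seed = 4, int_weights = TRUE)
  fitw <- fit_fixed_effects_ols(p$y, p$X, p$cell, p$w)
  idx <- rep(seq_along(p$y), p$w)
  fitx <- fit_fixed_effects_ols(p$y[idx], p$X[idx, ], p$cell[idx])
  expect_equal(fitw$coefficients, fitx$coefficients, tolerance = 1e-8)
})

test_that("constant-within-cell columns are absorbed, collinear ones dropped", {
  p <- make_random_panel(20, 4, seed = 5)
  treat <- rep(rep(0:1, 10), each = 4)
  X <- cbind(p$X, treat = treat, x1copy = p$X[, "x1"])
  fit <- fit_fixed_effects_ols(p$y, X, p$cell)
  expect_true("treat" %in% fit$absorbed)
  expect_true("x1copy" %in% fit$dropped)
  expect_equal(unname(fit$coefficients["x1"]),
               unname(bf_dummy_ols(p$y, p$X, p$cell)[1]), tolerance = 1e-8)
})

test_that("clustered vcov matches the direct block-sum sandwich", {
  # 12 observations, 3 clusters
  set.seed(6)
  X <- cbind(a = rnorm(12), b = rnorm(12))
  e <- rnorm(12); w <- runif(12, 0.5, 2); cl <- rep(1:3, each = 4)
  V <- cluster_robust_vcov(X, e, w, cl, k_params = 2)
  expect_equal(unclass(V)[1:2, 1:2], bf_cluster_vcov(X, e, w, cl, 2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(cluster_robust_vcov(X, e, w, rep(1, 12), k_params = 2),
               class = "defoeval_cluster_error")
})

test_that("singleton clusters reduce to the heteroskedasticity sandwich", {
  set.seed(7)
  X <- cbind(a = rnorm(30), b = runif(30))
  e <- rnorm(30); w <- rep(1, 30)
  V <- cluster_robust_vcov(X, e, w, cluster = 1:30, k_params = 2)
  B <- solve(crossprod(X))
  hc <- B %*% crossprod(X * e^2, X) %*% B * (30 / 29) * (29 / 28)
  expect_equal(unclass(V)[1:2, 1:2], hc, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("two-way clustering collapses to one-way on identical partitions", {
  set.seed(8)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  e <- rnorm(40); w <- rep(1, 40); cl <- rep(1:5, each = 8)
  V1 <- cluster_robust_vcov(X, e, w, cl, k_params = 2)
  V2 <- cluster_robust_vcov(X, e, w, cl, cluster2 = cl + 10, k_params = 2)
  expect_equal(unclass(V1)[1:2, 1:2], unclass(V2)[1:2, 1:2], tolerance = 1e-10)
})

test_that("clustered vcov agrees with an independent library implementation", {
  skip_if_not_installed("sandwich")
  set.seed(9)
  n <- 60
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), cl = rep(1:6, each = 10))
  d$y <- 1 + d$x1 - d$x2 + rnorm(n)
  fit <- lm(y ~ x1 + x2, data = d)
  X <- model.matrix(fit)
  V <- cluster_robust_vcov(X, resid(fit), rep(1, n), d$cl, k_params = 3)
  Vref <- sandwich::vcovCL(fit, cluster = d$cl, type = "HC1")
  expect_equal(unclass(V)[1:3, 1:3], unclass(Vref)[1:3, 1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("panel assembly follows the bookkeeping rules", {
  scen <- generate_landscape(tiny_config(seed = 10))
  cov_a <- aggregate_cover(scen$cover, 3)
  defo <- annual_deforestation(cov_a)
  mgmt <- aggregate_management(scen$management, 3)
  cells <- eligible_cells(mgmt, cov_a, 2005)
  tv <- analysis_time_variant(scen, cov_a)

  three <- cells[1:3, ]
  panel <- build_panel(three, defo, tv)
  expect_equal(nrow(panel), 48)   # 3 cells x 16 outcome years
  expect_equal(sort(unique(panel$year)), 2005:2020)

  # a control matched twice enters once per year with weight 2
  three$weight <- c(1, 1, 2)
  panel2 <- build_panel(three, defo, tv)
  expect_equal(nrow(panel2), 48)
  expect_true(all(panel2$weight[panel2$cell_id == three$cell_id[3]] == 2))

  expect_error(build_panel(three, defo, tv, years = 1999:2020),
               class = "defoeval_gap_error")
})

test_that("event study coefficients are invariant to the clustering scheme", {
  scen <- generate_landscape(tiny_config(seed = 12))
  cov_a <- aggregate_cover(scen$cover, 3)
  defo <- annual_deforestation(cov_a)
  mgmt <- aggregate_management(scen$management, 3)
  cells <- eligible_cells(mgmt, cov_a, 2005)
  panel <- build_panel(cells, defo, analysis_time_variant(scen, cov_a))
  f1 <- fit_event_study(panel, event_study_spec(cluster = "site"))
  f2 <- fit_event_study(panel, event_study_spec(cluster = c("site", "region")))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_false(identical(f1$table$std_error, f2$table$std_error))
  # single-restriction Wald is the squared t statistic by construction
  pre <- pretrend_test(f1)
  tt <- f1$table$statistic[f1$table$term == "CFM:Year"]
  expect_equal(pre$statistic, tt^2, tolerance = 1e-10)
})

test_that("the two-period DiD nails a hand example and ignores common shocks", {
  panel <- data.frame(
    cell_id = rep(c("t", "c"), each = 4),
    year = rep(c(2005, 2006, 2010, 2011), 2),
    Y = c(1, 1, 4, 4, 2, 2, 3, 3),  # treated rises 3, control rises 1
    CFM = rep(c(1, 0), each = 4),
    site = rep(c(1, 2), each = 4), region = 1, weight = 1)
  did <- fit_did(panel, pre_years = 2005:2006, crisis_years = 2010:2011)
  expect_equal(did$estimate, 2, tolerance = 1e-12)

  shifted <- panel
  shifted$Y[shifted$year >= 2010] <- shifted$Y[shifted$year >= 2010] + 7
  expect_equal(fit_did(shifted, 2005:2006, 2010:2011)$estimate, 2,
               tolerance = 1e-12)
  expect_error(fit_did(panel, 2005:2006, 2006:2007),
               class = "defoeval_argument_error")
})

test_that("a null moderator reproduces the base model exactly", {
  scen <- generate_landscape(tiny_config(seed = 13))
  cov_a <- aggregate_cover(scen$cover, 3)
  defo <- annual_deforestation(cov_a)
  mgmt <- aggregate_management(scen$management, 3)
  cells <- eligible_cells(mgmt, cov_a, 2005)
  panel <- build_panel(cells, defo, analysis_time_variant(scen, cov_a))
  spec <- event_study_spec()
  base <- fit_event_study(panel, spec)
  het <- heterogeneity_fit(panel, spec, rep(0, nrow(panel)))
  expect_equal(het$coefficients[names(base$coefficients)], base$coefficients,
               tolerance = 1e-10)
  expect_true(all(paste0("moderator:CFM:", spec$dummy_years) %in%
                    c(het$absorbed, het$dropped)))
})

test_that("median splits put exactly ceiling(n/2) cells below", {
  for (n in c(7, 8, 101)) {
    x <- rnorm(n)
    expect_equal(sum(median_split(x) == 0), ceiling(n / 2))
  }
  # ties broken by position: first occurrences go below
  expect_equal(median_split(c(1, 1, 1, 5)), c(0L, 0L, 1L, 1L))
})

test_that("hectare conversion follows the percentage arithmetic", {
  expect_equal(excess_loss_hectares(2, 1e5)$ha_per_year, 2000)
  expect_equal(excess_loss_hectares(0, 1e5)$ha_per_year, 0)
  # unrounded 2.42617 pp on 475,333 ha of forest gives ~11,532 ha/yr;
  # the rounded 2.43 gives ~11,551
  expect_equal(excess_loss_hectares(2.42617, 475333)$ha_per_year, 11532,
               tolerance = 1e-4)
  expect_equal(round(excess_loss_hectares(2.43, 475333)$ha_per_year), 11551)
  expect_error(excess_loss_hectares(2, -1), class = "defoeval_argument_error")
})
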