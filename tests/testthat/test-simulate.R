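test_that("identical seeds yield identical scenarios", {
  cfg <- tiny_config(seed = 77)
  s1 <- generate_landscape(cfg)
  s2 <- generate_landscape(cfg)
  expect_identical(s1, s2)
  s3 <- generate_landscape(tiny_config(seed = 78))
  expect_false(identical(s1$cover$cover, s3$cover$cover))
})

test_that("cover is monotone non-increasing and binary at base resolution", {
  scen <- generate_landscape(tiny_config(seed = 3))
  cov <- scen$cover$cover
  expect_true(all(cov %in% c(0, 100)))
  for (k in 2:dim(cov)[3])
    expect_true(all(cov[, , k] <= cov[, , k - 1]))
})

test_that("zero confounding yields balanced arms; defaults do not", {
  smds <- sapply(1:20, function(s)
    premat_smd(generate_landscape(balance_config(1000 + s, 0))))
  expect_true(all(abs(rowMeans(smds)) < 0.1))

  smd_def <- rowMeans(sapply(4:6, function(s)
    premat_smd(generate_landscape(sim_config(seed = s)))))
  access <- c("dist_road", "dist_village", "dist_cart_track", "popdens_2005")
  expect_gt(max(abs(smd_def[access])), 0.1)
  # CFM cells are the more accessible ones: closer to roads and villages
  expect_lt(smd_def[["dist_road"]], 0)
  expect_lt(smd_def[["dist_village"]], 0)
})

test_that("imbalance grows with the confounding scale", {
  mx <- sapply(c(0, 0.5, 1.25), function(sc) {
    mean(sapply(1:20, function(s) {
      smd <- premat_smd(generate_landscape(balance_config(200 + s, sc)))
      mean(abs(smd[score_covariates]))
    }))
  })
  expect_true(all(diff(mx) > 0))
})

test_that("rice prices are national: constant across cells within a year", {
  scen <- generate_landscape(tiny_config(seed = 9))
  cov_a <- aggregate_cover(scen$cover, 3)
  mgmt <- aggregate_management(scen$management, 3)
  cells <- eligible_cells(mgmt, cov_a, 2005)
  panel <- build_panel(cells, annual_deforestation(cov_a),
                       analysis_time_variant(scen, cov_a))
  per_year <- tapply(panel$rice_price_mean, panel$year,
                     function(v) length(unique(v)))
  expect_true(all(per_year == 1))
})

test_that("the true effect schedule mirrors the configuration exactly", {
  cfg0 <- tiny_config(seed = 1, delta_true = c())
  expect_true(all(true_effect_schedule(cfg0) == 0))

  cfg <- tiny_config(seed = 1)
  sched <- true_effect_schedule(cfg)
  expect_equal(sched[["2017"]], 0.0243)
  expect_equal(sched[["2009"]], 0)

  # round-trip through the YAML config echo
  dir <- withr::local_tempdir()
  scen <- generate_landscape(tiny_config(seed = 2))
  write_scenario(scen, dir)
  echo <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(unlist(echo$delta_true), cfg$delta_true)
  expect_error(sim_config(delta_true = c("1990" = 0.1)),
               class = "defoeval_argument_error")
})

test_that("an extreme negative hazard intercept freezes the forest", {
  scen <- generate_landscape(tiny_config(seed = 4, hazard_intercept = -30,
                                         delta_true = c(),
                                         year_shocks = c()))
  cov <- scen$cover$cover
  expect_equal(cov[, , dim(cov)[3]], cov[, , 1])
})

test_that("unit placement fails loudly when the grid cannot host the units", {
  expect_error(generate_landscape(sim_config(grid_rows = 30, grid_cols = 30,
                                             n_cfm_units = 50, n_mnp_units = 10,
                                             seed = 1)),
               class = "defoeval_sizing_error")
})

test_that("every cell belongs to at most one unit; overlaps are flagged only", {
  scen <- generate_landscape(tiny_config(seed = 6))
  uid <- scen$management$unit_id
  ov <- scen$management$overlap
  expect_true(all(is.na(uid[ov])))  # overlap cells belong to no unit
  expect_true(all(uid[!is.na(uid)] %in% scen$management$units$unit_id))
})
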