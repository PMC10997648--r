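# Config-driven orchestration: simulate -> outcomes -> sample -> match ->
# fit -> report, with per-stage seeds derived from one global seed, plain
# CSV/YAML artifacts, and a manifest with content digests so a rerun can be
# verified bit for bit.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic scenario.
#' @param resolution Analysis resolution in meters (90 or 270 by default;
#'   other multiples of 30 are accepted but non-standard).
#' @param n_treated,n_control_pool Sample sizes for the spatially balanced
#'   draw (clamped to availability with a message; the full-scale analysis
#'   used 12,000 treated and a 36,000-point comparison pool).
#' @param renewed_only Restrict CFM to renewed contracts.
#' @param matching_method `"genetic"`, `"mahalanobis"` or `"propensity"`.
#' @param ga_params Genetic-algorithm settings (see [genetic_match()]).
#' @param spec An [event_study_spec()].
#' @param years Outcome years.
#' @param seed Global seed; per-stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), resolution = 90,
                            n_treated = 12000, n_control_pool = 36000,
                            renewed_only = FALSE,
                            matching_method = c("genetic", "mahalanobis",
                                                "propensity"),
                            ga_params = list(), spec = event_study_spec(),
                            years = 2005:2020, seed = 1L) {
  matching_method <- match.arg(matching_method)
  if (resolution %% 30 != 0)
    stop_defoeval("analysis resolution must be a multiple of 30 m",
                  "defoeval_argument_error")
  if (!resolution %in% c(90, 270))
    message("note: non-standard analysis resolution ", resolution, " m")
  structure(list(sim = sim, resolution = resolution,
                 n_treated = n_treated, n_control_pool = n_control_pool,
                 renewed_only = renewed_only,
                 matching_method = matching_method, ga_params = ga_params,
                 spec = spec, years = as.integer(years),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

match_covariate_names <- function() {
  c("rice_suitability", "elevation", "slope", "precipitation",
    "dist_forest_edge_2005", "dist_village", "dist_urban", "dist_road",
    "dist_cart_track", "popdens_2005")
}

# Static matching covariates at the analysis resolution for a set of cells;
# the 2005 edge distance is computed from the analysis cover.
static_covariate_table <- function(scenario, cover_analysis, cells,
                                   baseline_year = 2005) {
  factor <- as.integer(round(cover_analysis$resolution / 30))
  d <- dim(cover_analysis$cover)
  lin <- (cells$col - 1L) * d[1] + cells$row
  cols <- lapply(setdiff(match_covariate_names(), "dist_forest_edge_2005"),
                 function(nm) {
    m <- block_mean(scenario$static[[nm]][seq_len(d[1] * factor),
                                          seq_len(d[2] * factor)], factor)
    m[lin]
  })
  names(cols) <- setdiff(match_covariate_names(), "dist_forest_edge_2005")
  edge <- distance_to_forest_edge(cover_analysis, baseline_year)
  cols$dist_forest_edge_2005 <- edge[lin]
  as.data.frame(cols)[match_covariate_names()]
}

write_csv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  path
}

# Long-format CSV of a cover/deforestation array stack.
write_grid_series <- function(arr3, years, path) {
  d <- dim(arr3)
  dt <- data.table::data.table(
    row = rep(rep(seq_len(d[1]), d[2]), d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    year = rep(years, each = d[1] * d[2]),
    value = as.vector(arr3))
  data.table::fwrite(dt, path)
  path
}

#' Write a synthetic scenario to a directory
#'
#' Per-year cover layers as a long CSV, the unit table, the static
#' covariate grids, national series, and a YAML echo of the configuration,
#' all under one scenario directory.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- scenario$truth
  write_grid_series(scenario$cover$cover, scenario$cover$years,
                    file.path(dir, "cover.csv"))
  write_csv(scenario$management$units, file.path(dir, "units.csv"))
  stat <- data.frame(row = rep(seq_len(cfg$grid_rows), cfg$grid_cols),
                     col = rep(seq_len(cfg$grid_cols), each = cfg$grid_rows))
  for (nm in names(scenario$static))
    stat[[nm]] <- as.vector(scenario$static[[nm]])
  stat$unit_id <- as.vector(scenario$management$unit_id)
  stat$overlap <- as.vector(scenario$management$overlap)
  write_csv(stat, file.path(dir, "static_covariates.csv"))
  write_csv(scenario$time_variant$national, file.path(dir, "national_series.csv"))
  cfg_out <- cfg
  class(cfg_out) <- NULL
  cfg_out$psi_true <- as.list(cfg_out$psi_true)
  cfg_out$delta_true <- as.list(cfg_out$delta_true)
  cfg_out$year_shocks <- as.list(cfg_out$year_shocks)
  cfg_out$confounding_strengths <- as.list(cfg_out$confounding_strengths)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Run the full pipeline
#'
#' Simulates (or reuses) a scenario, constructs outcomes at the configured
#' resolution, draws spatially balanced treated/control samples, matches,
#' fits the event study and the two-period DiD, and writes every artifact
#' plus a manifest of content digests under `out_dir`. Rerunning with the
#' same configuration reproduces all numeric outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(nm) derive_seed(config$seed, nm)
  artifacts <- character()
  log_line <- function(...) message("[pipeline] ", sprintf(...))

  # simulate
  sim_cfg <- config$sim
  sim_cfg$seed <- stage("simulate")
  scen <- generate_landscape(sim_cfg)
  scen_dir <- file.path(out_dir, "scenario")
  write_scenario(scen, scen_dir)
  artifacts <- c(artifacts, list.files(scen_dir, full.names = TRUE))
  log_line("scenario: %d x %d cells, %d units", sim_cfg$grid_rows,
           sim_cfg$grid_cols, nrow(scen$management$units))

  # outcomes
  factor <- as.integer(config$resolution / 30)
  cov_a <- aggregate_cover(scen$cover, factor)
  defo <- annual_deforestation(cov_a)
  f <- write_grid_series(defo$value, defo$years,
                         file.path(out_dir, "deforestation.csv"))
  artifacts <- c(artifacts, f)

  # sample
  mgmt <- aggregate_management(scen$management, factor)
  baseline <- min(config$years)
  cfm_cells <- eligible_cells(mgmt, cov_a, baseline, kinds = "CFM",
                              renewed_only = config$renewed_only)
  mnp_cells <- eligible_cells(mgmt, cov_a, baseline, kinds = "MNP")
  if (nrow(cfm_cells) == 0 || nrow(mnp_cells) == 0)
    stop_defoeval("sampling stage: no eligible cells",
                  "defoeval_empty_eligibility")
  nt <- min(config$n_treated, nrow(cfm_cells))
  np <- min(config$n_control_pool, nrow(mnp_cells))
  if (nt < config$n_treated || np < config$n_control_pool)
    log_line("sample sizes clamped to availability: %d treated, %d pool", nt, np)
  treated <- spatially_balanced_sample(cfm_cells, nt, stage("sample_cfm"))
  pool <- spatially_balanced_sample(mnp_cells, np, stage("sample_mnp"))
  f <- write_csv(rbind(treated, pool), file.path(out_dir, "sample_points.csv"))
  artifacts <- c(artifacts, f)
  log_line("sampled %d CFM and %d MNP cells", nrow(treated), nrow(pool))

  # match; treated cells in zones with no comparison cells cannot be
  # matched exactly within zone and are set aside with a note
  orphan <- !treated$vegetation_zone %in% unique(pool$vegetation_zone)
  if (any(orphan)) {
    log_line("dropping %d treated cell(s) in zone(s) %s with no comparison cells",
             sum(orphan),
             paste(sort(unique(treated$vegetation_zone[orphan])), collapse = ","))
    treated <- treated[!orphan, ]
  }
  xt <- static_covariate_table(scen, cov_a, treated, baseline)
  xc <- static_covariate_table(scen, cov_a, pool, baseline)
  matched <- switch(config$matching_method,
    genetic = genetic_match(xt, xc, treated$vegetation_zone,
                            pool$vegetation_zone, config$ga_params,
                            seed = stage("match")),
    mahalanobis = match_nearest(xt, xc, treated$vegetation_zone,
                                pool$vegetation_zone, "mahalanobis",
                                seed = stage("match")),
    propensity = match_nearest(xt, xc, treated$vegetation_zone,
                               pool$vegetation_zone, "propensity",
                               seed = stage("match")))
  bal <- balance_table(xt, xc, matched)
  pairs_out <- matched$pairs
  pairs_out$treated_cell <- treated$cell_id[pairs_out$treated]
  pairs_out$control_cell <- pool$cell_id[pairs_out$control]
  artifacts <- c(artifacts,
                 write_csv(pairs_out, file.path(out_dir, "matched_pairs.csv")),
                 write_csv(bal, file.path(out_dir, "balance.csv")))
  log_line("matching (%s): max|SMD| %.3f -> %.3f", config$matching_method,
           max(abs(bal$smd_before)), max(abs(bal$smd_after)))

  # fit
  pts <- matched_points(treated, pool, matched)
  tv <- analysis_time_variant(scen, cov_a, config$years)
  panel <- build_panel(pts, defo, tv, config$years)
  fit <- fit_event_study(panel, config$spec)
  did <- fit_did(panel)
  pre <- pretrend_test(fit)
  artifacts <- c(artifacts,
                 write_csv(fit$table, file.path(out_dir, "event_study.csv")),
                 write_csv(yearly_effects(fit), file.path(out_dir, "yearly_effects.csv")),
                 write_csv(data.frame(estimate = did$estimate,
                                      std_error = did$std_error,
                                      statistic = did$statistic,
                                      p_value = did$p_value),
                           file.path(out_dir, "did.csv")))
  log_line("event study: %d obs, %d cells, %d clusters", fit$n_obs,
           fit$n_cells, fit$n_clusters)

  manifest <- list(
    seed = config$seed, resolution = config$resolution,
    renewed_only = config$renewed_only,
    matching_method = config$matching_method,
    stage_seeds = list(simulate = stage("simulate"),
                       sample_cfm = stage("sample_cfm"),
                       sample_mnp = stage("sample_mnp"),
                       match = stage("match")),
    n_treated = nrow(treated), n_control_pool = nrow(pool),
    n_unique_controls = length(matched$control_weights),
    pretrend_p = pre$p_value,
    files = lapply(stats::setNames(nm = sort(basename(artifacts))), function(b) {
      p <- artifacts[basename(artifacts) == b][1]
      list(path = b, md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scenario = scen, cover_analysis = cov_a,
                 deforestation = defo, treated = treated, pool = pool,
                 matched = matched, balance = bal, panel = panel,
                 fit = fit, did = did, pretrend = pre, manifest = manifest))
}

#' Bundled forest-area summary for Madagascar
#'
#' Published summary areas of forest cover in Madagascar used by the worked
#' examples: national, MNP and CFM totals for 2005 and 2020, and the CFM
#' area in 2008 (the year preceding the crisis) used for the
#' hectares-per-year conversion.
#'
#' @return Data frame: `scope`, `year`, `area_ha`.
#' @export
madagascar_forest_areas <- function() {
  utils::read.csv(system.file("extdata", "madagascar_forest_areas.csv",
                              package = "defoeval"))
}
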