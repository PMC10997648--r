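# Monte Carlo experiments over the synthetic pipeline: parameter recovery,
# placebo size, confidence-interval coverage, pre-trend power.

#' Run one synthetic scenario through the analysis pipeline
#'
#' Convenience wrapper used by the Monte Carlo experiments and the worked
#' examples: generate a landscape, aggregate cover to the analysis
#' resolution, construct outcomes, select eligible cells, and fit the event
#' study. Matching is optional here: the grid-cell fixed effects already
#' absorb all static confounding, so effect recovery does not require it;
#' the matching stage is exercised and assessed separately.
#'
#' @param config A [sim_config()].
#' @param spec An [event_study_spec()].
#' @param years Outcome years.
#' @param renewed_only Restrict CFM cells to renewed contracts.
#' @param match_method `"mahalanobis"` (default: nearest-neighbour matching
#'   on the static covariates before fitting, as in the full pipeline),
#'   `"genetic"`, `"propensity"`, or `"none"` (fixed effects only).
#' @return List: `fit` (`event_study_result`), `panel`, `cells`, `scenario`,
#'   `cover_analysis`, `deforestation`, and (when matched) `matched`,
#'   `balance`.
#' @export
run_scenario_analysis <- function(config, spec = event_study_spec(),
                                  years = 2005:2020, renewed_only = FALSE,
                                  match_method = "mahalanobis") {
  scen <- generate_landscape(config)
  cov_a <- aggregate_cover(scen$cover, config$analysis_factor)
  defo <- annual_deforestation(cov_a)
  mgmt <- aggregate_management(scen$management, config$analysis_factor)
  baseline <- min(years)
  matched <- bal <- NULL
  if (match_method == "none") {
    cells <- eligible_cells(mgmt, cov_a, baseline,
                            renewed_only = renewed_only)
    if (nrow(cells) == 0)
      stop_defoeval("no eligible cells in scenario",
                    "defoeval_empty_eligibility")
  } else {
    treated <- eligible_cells(mgmt, cov_a, baseline, kinds = "CFM",
                              renewed_only = renewed_only)
    pool <- eligible_cells(mgmt, cov_a, baseline, kinds = "MNP")
    if (nrow(treated) == 0 || nrow(pool) == 0)
      stop_defoeval("no eligible cells in scenario",
                    "defoeval_empty_eligibility")
    xt <- static_covariate_table(scen, cov_a, treated, baseline)
    xc <- static_covariate_table(scen, cov_a, pool, baseline)
    matched <- if (match_method == "genetic") {
      genetic_match(xt, xc, treated$vegetation_zone, pool$vegetation_zone,
                    seed = derive_seed(config$seed, "match"))
    } else {
      match_nearest(xt, xc, treated$vegetation_zone, pool$vegetation_zone,
                    match_method, seed = derive_seed(config$seed, "match"))
    }
    bal <- balance_table(xt, xc, matched)
    cells <- matched_points(treated, pool, matched)
  }
  tv <- analysis_time_variant(scen, cov_a, years)
  panel <- build_panel(cells, defo, tv, years)
  fit <- fit_event_study(panel, spec)
  list(fit = fit, panel = panel, cells = cells, scenario = scen,
       cover_analysis = cov_a, deforestation = defo,
       matched = matched, balance = bal)
}

#' Monte Carlo replication of the event study
#'
#' Repeats the full simulate-and-estimate cycle with independent seeds and
#' collects the yearly CFM effect estimates, their clustered standard
#' errors, confidence-interval hits against the configured truth, 10%-level
#' rejections, and the pre-trend test. Everything downstream of the seed is
#' recomputed each repetition.
#'
#' @param config Base [sim_config()]; each repetition swaps in a derived
#'   seed.
#' @param n_reps Number of repetitions.
#' @param seed Master seed for the repetition stream.
#' @param spec An [event_study_spec()].
#' @param years Outcome years.
#' @param match_method Matching applied before each fit (see
#'   [run_scenario_analysis()]).
#' @return List: `estimates`, `std_errors` (reps x dummy years), `truth`
#'   (on the 0-100 outcome scale), `ci_cover` and `reject10` (logical
#'   matrices), `pretrend_p` (vector), `n_cells` (vector).
#' @export
mc_event_study <- function(config, n_reps = 200, seed = 1L,
                           spec = event_study_spec(), years = 2005:2020,
                           match_method = "mahalanobis") {
  dy <- spec$dummy_years
  truth <- 100 * true_effect_schedule(config)[as.character(dy)]
  est <- se <- matrix(NA_real_, n_reps, length(dy),
                      dimnames = list(NULL, paste0("CFM:", dy)))
  pre_p <- numeric(n_reps)
  ncells <- integer(n_reps)
  dfree <- matrix(NA_real_, n_reps, length(dy))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("rep", r))
    res <- run_scenario_analysis(cfg, spec, years, match_method = match_method)
    d <- delta_effects(res$fit)
    idx <- match(paste0("CFM:", dy), d$term)
    est[r, ] <- d$estimate[idx]
    se[r, ] <- d$std_error[idx]
    dfree[r, ] <- res$fit$df
    pre_p[r] <- pretrend_test(res$fit)$p_value
    ncells[r] <- res$fit$n_cells
  }
  q <- qt(1 - (1 - spec$ci_level) / 2, dfree)
  ci_cover <- abs(sweep(est, 2, truth)) <= q * se
  reject10 <- 2 * pt(-abs(est / se), dfree) < 0.10
  list(estimates = est, std_errors = se, truth = truth,
       ci_cover = ci_cover, reject10 = reject10,
       pretrend_p = pre_p, n_cells = ncells)
}

#' Summarize a Monte Carlo run
#'
#' @param mc Output of [mc_event_study()].
#' @return Data frame per dummy year: truth, mean and SD of the estimates,
#'   Monte Carlo standard error of the mean, bias in MC-SE units, CI
#'   coverage, and 10%-level rejection rate.
#' @export
mc_summary <- function(mc) {
  n <- nrow(mc$estimates)
  mean_est <- colMeans(mc$estimates)
  sd_est <- apply(mc$estimates, 2, sd)
  mcse <- sd_est / sqrt(n)
  data.frame(term = colnames(mc$estimates),
             truth = as.numeric(mc$truth),
             mean_estimate = mean_est, sd_estimate = sd_est,
             mc_se = mcse,
             bias_in_mcse = (mean_est - as.numeric(mc$truth)) / mcse,
             ci_coverage = colMeans(mc$ci_cover),
             reject10 = colMeans(mc$reject10),
             row.names = NULL)
}
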