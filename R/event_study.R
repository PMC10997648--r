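# The event study: yearly crisis/post-crisis effects with grid-cell fixed
# effects and site-clustered errors, plus the two-period DiD variant, the
# pre-trend check, heterogeneity interactions, and the conversion of
# coefficients to hectares.

#' Event-study specification
#'
#' The regression is
#' `Y_it = tau1 year_t + tau2 year_t CFM_i + gamma_t 1{t} + delta_t CFM_i 1{t}
#'  + psi X_it + mu_i + e_it`
#' with year dummies only for the crisis/post-crisis years (the pre-crisis
#' years are the reference period, controlled linearly by the trend terms),
#' cell fixed effects `mu_i`, and cluster-robust errors. The CFM main effect
#' is time-invariant and absorbed by the fixed effects. The `delta_t`
#' coefficients — the CFM interactions with each crisis/post-crisis year —
#' are the quantities of interest.
#'
#' @param dummy_years Years receiving event dummies (default 2010-2020).
#' @param covariates Names of time-variant control columns in the panel.
#' @param cluster `"site"` or `c("site", "region")` for two-way clustering.
#' @param ci_level Confidence level (default 0.90, two-sided).
#' @return An `event_study_spec` list.
#' @export
event_study_spec <- function(dummy_years = 2010:2020,
                             covariates = c("dist_forest_edge", "popdens",
                                            "rice_price_mean", "rice_price_sd",
                                            "drought_pdsi", "max_precip",
                                            "max_temp", "max_wind"),
                             cluster = "site",
                             ci_level = 0.90) {
  stopifnot(all(cluster %in% c("site", "region")), length(cluster) %in% 1:2,
            ci_level > 0, ci_level < 1)
  structure(list(dummy_years = as.integer(dummy_years),
                 covariates = covariates,
                 cluster = cluster, ci_level = ci_level),
            class = "event_study_spec")
}

# Assemble the event-study design matrix from a panel.
event_design <- function(panel, spec, extra = NULL) {
  dy <- spec$dummy_years
  X <- cbind(Year = panel$year,
             `CFM:Year` = panel$CFM * panel$year)
  for (y in dy) X <- cbind(X, (panel$year == y) * 1)
  colnames(X)[seq(3, 2 + length(dy))] <- dy
  for (y in dy) X <- cbind(X, panel$CFM * (panel$year == y))
  colnames(X)[seq(3 + length(dy), 2 + 2 * length(dy))] <- paste0("CFM:", dy)
  miss <- setdiff(spec$covariates, names(panel))
  if (length(miss))
    stop_defoeval(paste("panel lacks covariates:", paste(miss, collapse = ", ")),
                  "defoeval_gap_error")
  X <- cbind(X, as.matrix(panel[spec$covariates]))
  if (!is.null(extra)) X <- cbind(X, extra)
  X
}

signif_code <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", ""))
}

#' Fit the event study
#'
#' Runs the within (fixed-effects) regression of [event_study_spec()] on a
#' panel from [build_panel()], with CR1 cluster-robust standard errors,
#' t-distribution p-values on `G - 1` degrees of freedom (`G` = number of
#' clusters in the smaller dimension), and two-sided confidence intervals at
#' the spec's level.
#'
#' @param panel Panel data frame.
#' @param spec An [event_study_spec()].
#' @param extra Optional extra design columns (used by [heterogeneity_fit()]).
#' @return An `event_study_result`: coefficient `table` (estimate, SE,
#'   statistic, p-value, CI, significance code), `vcov`, `coefficients`,
#'   `df`, `rmse`, `within_r2`, `n_obs`, `n_cells`, `n_clusters`,
#'   `absorbed`, `dropped`, `psd_repaired`, `spec`.
#' @export
fit_event_study <- function(panel, spec = event_study_spec(), extra = NULL) {
  X <- event_design(panel, spec, extra)
  fit <- fit_fixed_effects_ols(panel$Y, X, panel$cell_id, panel$weight)
  cl2 <- if (length(spec$cluster) == 2) panel$region else NULL
  V <- cluster_robust_vcov(fit$Xd, fit$residuals, fit$weights,
                           cluster = panel$site, cluster2 = cl2,
                           k_params = fit$k_params)
  G <- attr(V, "n_clusters")
  df <- G - 1
  se <- sqrt(diag(V))
  est <- fit$coefficients
  stat <- est / se
  p <- 2 * pt(-abs(stat), df)
  half <- qt(1 - (1 - spec$ci_level) / 2, df) * se
  w <- fit$weights
  rss <- sum(w * fit$residuals^2)
  tss <- sum(w * fit$yd^2)
  out <- list(
    table = data.frame(term = names(est), estimate = est, std_error = se,
                       statistic = stat, p_value = p,
                       ci_low = est - half, ci_high = est + half,
                       signif = signif_code(p), row.names = NULL),
    coefficients = est, vcov = V, df = df,
    rmse = sqrt(rss / (fit$n_obs - fit$k_params)),
    within_r2 = 1 - rss / tss,
    n_obs = fit$n_obs, n_cells = fit$n_cells, n_clusters = G,
    absorbed = fit$absorbed, dropped = fit$dropped,
    psd_repaired = attr(V, "psd_repaired"),
    spec = spec)
  class(out) <- "event_study_result"
  out
}

#' @export
print.event_study_result <- function(x, digits = 4, ...) {
  cat("Event study (cell fixed effects, cluster-robust SEs)\n")
  tb <- x$table
  tb$estimate <- signif(tb$estimate, digits)
  tb$std_error <- signif(tb$std_error, digits)
  tb$statistic <- round(tb$statistic, 3)
  tb$p_value <- round(tb$p_value, 4)
  print(tb[c("term", "estimate", "std_error", "statistic", "p_value", "signif")],
        row.names = FALSE)
  cat(sprintf("Signif. codes: '***' 0.001 '**' 0.01 '*' 0.05 '.' 0.1\n"))
  cat(sprintf("n = %d (%d cells, %d clusters); RMSE %.6g; within R2 %.6g\n",
              x$n_obs, x$n_cells, x$n_clusters, x$rmse, x$within_r2))
  if (length(x$absorbed))
    cat("Absorbed by fixed effects:", paste(x$absorbed, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("Dropped (collinear):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Yearly effect paths for plotting
#'
#' Extracts, per event year, the comparison-arm effect (`gamma_t`, the MNP
#' path) and the treated-arm effect (`gamma_t + delta_t`, the CFM path) with
#' confidence intervals from the clustered variance — the numbers an
#' event-study figure displays.
#'
#' @param result An `event_study_result`.
#' @return Data frame: `year`, `arm` (`"MNP"`/`"CFM"`), `effect`, `ci_low`,
#'   `ci_high`, `ci_level`.
#' @export
yearly_effects <- function(result) {
  stopifnot(inherits(result, "event_study_result"))
  spec <- result$spec
  q <- qt(1 - (1 - spec$ci_level) / 2, result$df)
  rows <- lapply(spec$dummy_years, function(y) {
    g <- as.character(y); d <- paste0("CFM:", y)
    if (!g %in% names(result$coefficients)) return(NULL)
    eg <- result$coefficients[[g]]
    sg <- sqrt(result$vcov[g, g])
    out <- data.frame(year = y, arm = "MNP", effect = eg,
                      ci_low = eg - q * sg, ci_high = eg + q * sg)
    if (d %in% names(result$coefficients)) {
      ec <- eg + result$coefficients[[d]]
      sc <- sqrt(result$vcov[g, g] + result$vcov[d, d] + 2 * result$vcov[g, d])
      out <- rbind(out, data.frame(year = y, arm = "CFM", effect = ec,
                                   ci_low = ec - q * sc, ci_high = ec + q * sc))
    }
    out
  })
  out <- do.call(rbind, rows)
  out$ci_level <- spec$ci_level
  rownames(out) <- NULL
  out
}

#' Extract the CFM-by-year effects
#'
#' @param result An `event_study_result`.
#' @return The `table` rows for the `CFM:<year>` interaction terms, with a
#'   numeric `year` column.
#' @export
delta_effects <- function(result) {
  stopifnot(inherits(result, "event_study_result"))
  tb <- result$table[grepl("^CFM:[0-9]{4}$", result$table$term), ]
  tb$year <- as.integer(sub("^CFM:", "", tb$term))
  rownames(tb) <- NULL
  tb
}

#' Two-period difference-in-differences
#'
#' Collapses the panel to cell-by-period means (pre-crisis vs crisis) and
#' estimates the CFM-by-crisis interaction with cell fixed effects and
#' site-clustered errors. The DiD averages what the event study traces year
#' by year; it serves as the conventional cross-check.
#'
#' @param panel Panel data frame.
#' @param pre_years,crisis_years Disjoint year sets (defaults 2005-2009 and
#'   2010-2014).
#' @return List: `estimate`, `std_error`, `statistic`, `p_value`, `df`,
#'   `n_cells`.
#' @export
fit_did <- function(panel, pre_years = 2005:2009, crisis_years = 2010:2014) {
  if (length(intersect(pre_years, crisis_years)))
    stop_defoeval("pre and crisis year sets must be disjoint",
                  "defoeval_argument_error")
  keep <- panel$year %in% c(pre_years, crisis_years)
  p <- panel[keep, ]
  p$period <- as.integer(p$year %in% crisis_years)
  key <- paste(p$cell_id, p$period, sep = "\r")
  agg <- data.frame(
    Y = rowsum(p$Y * p$weight, key)[, 1] / rowsum(p$weight, key)[, 1])
  first <- !duplicated(key)
  ord <- match(sort(unique(key)), key[first])
  meta <- p[first, ][ord, ]
  agg$cell_id <- meta$cell_id; agg$period <- meta$period
  agg$CFM <- meta$CFM; agg$site <- meta$site; agg$weight <- meta$weight
  X <- cbind(period = agg$period, `CFM:period` = agg$CFM * agg$period)
  fit <- fit_fixed_effects_ols(agg$Y, X, agg$cell_id, agg$weight)
  V <- cluster_robust_vcov(fit$Xd, fit$residuals, fit$weights, agg$site,
                           k_params = fit$k_params)
  G <- attr(V, "n_clusters")
  est <- fit$coefficients[["CFM:period"]]
  se <- sqrt(V["CFM:period", "CFM:period"])
  list(estimate = est, std_error = se, statistic = est / se,
       p_value = 2 * pt(-abs(est / se), G - 1), df = G - 1,
       n_cells = fit$n_cells)
}

#' Pre-trend (parallel trends) test
#'
#' Wald test of the differential linear pre-crisis trend: the `CFM:Year`
#' coefficient against zero, using the clustered variance. With event
#' dummies covering every crisis/post-crisis year, this coefficient is
#' identified from the pre-crisis years only, so it is the event-study
#' check of the parallel-trends assumption.
#'
#' @param result An `event_study_result`.
#' @return List: `statistic` (Wald, 1 df), `p_value`, `df` (denominator).
#' @export
pretrend_test <- function(result) {
  stopifnot(inherits(result, "event_study_result"))
  if (!"CFM:Year" %in% names(result$coefficients))
    stop_defoeval("CFM:Year was dropped; pre-trend not testable",
                  "defoeval_not_testable")
  t <- result$coefficients[["CFM:Year"]] /
    sqrt(result$vcov["CFM:Year", "CFM:Year"])
  list(statistic = t^2, p_value = 2 * pt(-abs(t), result$df),
       df = result$df)
}

#' Median split of a moderator
#'
#' Binary 0/1 split at the median: cells with rank at most `ceiling(n/2)`
#' (ties broken by cell order) get 0 (below median), the rest 1.
#'
#' @param x Numeric vector (one value per cell).
#' @return Integer 0/1 vector.
#' @export
median_split <- function(x) {
  n <- length(x)
  lo <- order(x, seq_len(n))[seq_len(ceiling(n / 2))]
  out <- rep(1L, n)
  out[lo] <- 0L
  out
}

#' Event study with moderator interactions
#'
#' Augments the event-study design with `moderator x CFM x year-dummy`
#' triple interactions, exploring whether the yearly CFM effects vary with
#' a static cell attribute (e.g. distance to urban centers). Continuous
#' moderators are standardized; `split = "median"` applies [median_split()]
#' first. A moderator that is constant (all-zero interactions) leaves the
#' base model untouched, with the dropped columns reported.
#'
#' @param panel Panel data frame.
#' @param spec An [event_study_spec()].
#' @param moderator Name of a panel column, or a vector of per-row values.
#' @param split `"standardize"` (default), `"median"`, or `"none"` (use the
#'   supplied values as-is, e.g. when they are already on a meaningful
#'   scale).
#' @return An `event_study_result` whose table includes the
#'   `<moderator>:CFM:<year>` terms.
#' @export
heterogeneity_fit <- function(panel, spec = event_study_spec(), moderator,
                              split = c("standardize", "median", "none")) {
  split <- match.arg(split)
  if (is.character(moderator) && length(moderator) == 1) {
    nm <- moderator
    if (!nm %in% names(panel))
      stop_defoeval(sprintf("moderator '%s' not in panel", nm),
                    "defoeval_argument_error")
    m <- panel[[nm]]
  } else {
    nm <- "moderator"
    m <- moderator
    stopifnot(length(m) == nrow(panel))
  }
  cells <- !duplicated(panel$cell_id)
  if (split == "median") {
    cuts <- median_split(m[cells])
    m <- cuts[match(panel$cell_id, panel$cell_id[cells])]
  } else if (split == "none") {
    # keep supplied values
  } else {
    s <- sd(m[cells])
    m <- if (is.finite(s) && s > 0) (m - mean(m[cells])) / s else m * 0
  }
  extra <- vapply(spec$dummy_years,
                  function(y) m * panel$CFM * (panel$year == y),
                  numeric(nrow(panel)))
  colnames(extra) <- paste0(nm, ":CFM:", spec$dummy_years)
  fit_event_study(panel, spec, extra = extra)
}

#' Convert yearly effect coefficients to hectares
#'
#' A coefficient on the 0-100 outcome scale is a percentage of cell area
#' lost per year; divided by 100 and multiplied by the forest area it gives
#' excess loss in hectares per year. For example an effect of 2.43
#' percentage points on 475,333 ha of forest is 11,551 ha/year (the
#' unrounded 2.42617 gives 11,532).
#'
#' @param delta Yearly effect(s) in percentage points (0-100 outcome scale).
#' @param area_ha Forest area in hectares.
#' @return List: `ha_per_year` (per input coefficient) and `total_ha`.
#' @export
excess_loss_hectares <- function(delta, area_ha) {
  if (!is.numeric(area_ha) || any(area_ha < 0))
    stop_defoeval("forest area must be non-negative", "defoeval_argument_error")
  hpy <- delta / 100 * area_ha
  list(ha_per_year = hpy, total_ha = sum(hpy))
}
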