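# Panel construction and the fixed-effects / cluster-robust estimation
# machinery underlying the event study.

#' Assemble the cell-year panel
#'
#' One row per sampled (or matched) cell per outcome year: the deforestation
#' outcome `Y` (percentage points of cell area lost that year), the
#' treatment indicator `CFM`, the time-variant controls, the site and region
#' cluster ids, and the control-reuse weight. Matched controls appear once
#' per year with their reuse count as weight, the with-replacement ATT
#' bookkeeping that the clustered standard errors then account for.
#'
#' @param points Data frame of analysis cells: `cell_id`, `row`, `col`,
#'   `treatment`, `unit_id`, `region_id`, and optionally `weight`
#'   (default 1). See [matched_points()] for building this from a matching.
#' @param deforestation A `deforestation_series` at the analysis resolution.
#' @param time_variant Cell-year covariates at the analysis resolution, as
#'   returned by [analysis_time_variant()].
#' @param years Outcome years (default 2005-2020).
#' @return A `data.frame` panel, one row per cell-year.
#' @export
build_panel <- function(points, deforestation, time_variant,
                        years = 2005:2020) {
  stopifnot(inherits(deforestation, "deforestation_series"))
  miss_y <- setdiff(years, deforestation$years)
  if (length(miss_y))
    stop_defoeval(paste("outcome years missing from deforestation series:",
                        paste(miss_y, collapse = ", ")),
                  "defoeval_gap_error")
  if (is.null(points$weight)) points$weight <- 1
  nc_grid <- ncol(deforestation$value[, , 1])
  n <- nrow(points); ny <- length(years)

  lin <- (points$col - 1L) * nrow(deforestation$value[, , 1]) + points$row
  ymat <- vapply(as.character(years),
                 function(y) deforestation$value[, , y][lin], numeric(n))

  panel <- data.frame(
    cell_id = rep(points$cell_id, ny),
    year = rep(years, each = n),
    Y = as.vector(ymat),
    CFM = rep(points$treatment, ny),
    site = rep(points$unit_id, ny),
    region = rep(points$region_id, ny),
    weight = rep(points$weight, ny))

  for (nm in setdiff(names(time_variant), c("years", "national"))) {
    arr <- time_variant[[nm]]
    gaps <- setdiff(years, as.integer(dimnames(arr)[[3]]))
    if (length(gaps))
      stop_defoeval(sprintf("covariate '%s' missing years: %s", nm,
                            paste(gaps, collapse = ", ")),
                    "defoeval_gap_error")
    v <- vapply(as.character(years), function(y) arr[, , y][lin], numeric(n))
    panel[[nm]] <- as.vector(v)
  }
  nat <- time_variant$national
  if (!is.null(nat)) {
    gaps <- setdiff(years, nat$year)
    if (length(gaps))
      stop_defoeval(paste("national series missing years:",
                          paste(gaps, collapse = ", ")),
                    "defoeval_gap_error")
    for (nm in setdiff(names(nat), "year"))
      panel[[nm]] <- nat[[nm]][match(panel$year, nat$year)]
  }
  if (any(!is.finite(panel$Y)))
    stop_defoeval("non-finite outcome values", "defoeval_validation_error")
  panel
}

#' Combine treated cells and matched controls into analysis points
#'
#' @param treated Data frame of treated cells (rows of the sampling output).
#' @param controls Data frame of the control pool the matching indexed into.
#' @param matched A `matched_sample`; `pairs$control` must index rows of
#'   `controls`.
#' @return Points data frame: all treated cells with weight 1 plus each
#'   unique matched control once with its reuse count as weight.
#' @export
matched_points <- function(treated, controls, matched) {
  stopifnot(inherits(matched, "matched_sample"))
  wtab <- table(matched$pairs$control)
  ctrl <- controls[as.integer(names(wtab)), ]
  ctrl$weight <- as.numeric(wtab)
  treated$weight <- 1
  rbind(treated, ctrl)
}

#' Time-variant covariates at the analysis resolution
#'
#' Aggregates the simulated base-resolution cell-year fields by block means
#' and computes the annually updated distance to the forest edge from the
#' analysis-resolution cover (forest = cover > 0). For outcome year *t* the
#' edge distance of year *t - 1* is used: the covariate predates the loss it
#' helps explain.
#'
#' @param scenario A `synthetic_scenario`.
#' @param cover_analysis The aggregated [forest_cover_series()] the outcomes
#'   are computed from.
#' @param years Outcome years.
#' @return Named list of cell-year arrays plus the national series;
#'   suitable for [build_panel()].
#' @export
analysis_time_variant <- function(scenario, cover_analysis,
                                  years = 2005:2020) {
  factor <- as.integer(round(cover_analysis$resolution / 30))
  tv <- scenario$time_variant
  d <- dim(cover_analysis$cover)
  agg <- function(arr) {
    out <- array(0, c(d[1], d[2], length(years)),
                 dimnames = list(NULL, NULL, years))
    for (y in years)
      out[, , as.character(y)] <-
        block_mean(arr[seq_len(d[1] * factor), seq_len(d[2] * factor),
                       as.character(y)], factor)
    out
  }
  edge <- array(0, c(d[1], d[2], length(years)),
                dimnames = list(NULL, NULL, years))
  for (y in years)
    edge[, , as.character(y)] <- distance_to_forest_edge(cover_analysis, y - 1)
  list(dist_forest_edge = edge,
       popdens = agg(tv$popdens),
       drought_pdsi = agg(tv$drought_pdsi),
       max_precip = agg(tv$max_precip),
       max_temp = agg(tv$max_temp),
       max_wind = agg(tv$max_wind),
       national = tv$national)
}

#' Fixed-effects (within) weighted least squares
#'
#' Absorbs one fixed effect per cell by subtracting cell-level weighted
#' means from the outcome and every regressor, then runs weighted least
#' squares on the transformed data — numerically identical to the
#' dummy-variable formulation. Columns with no within-cell variation (e.g.
#' the treatment indicator itself) are reported as absorbed; columns that
#' become collinear after absorption are dropped and named.
#'
#' @param y Outcome vector.
#' @param X Design matrix (no intercept; it is absorbed).
#' @param cell Fixed-effect grouping (cell id per row).
#' @param weights Non-negative observation weights (default 1).
#' @return List: `coefficients`, `residuals`, `Xd` (demeaned kept columns),
#'   `absorbed`, `dropped`, `n_obs`, `n_cells`, `k_params` (estimated slopes
#'   + absorbed fixed effects), `weights`, `yd` (demeaned outcome).
#' @export
fit_fixed_effects_ols <- function(y, X, cell, weights = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(cell) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop_defoeval("negative weights", "defoeval_argument_error")
  cell <- as.character(cell)

  wsum <- rowsum(weights, cell)[, 1]
  demean <- function(v) {
    m <- rowsum(v * weights, cell) / wsum
    v - m[cell, , drop = FALSE]
  }
  yd <- demean(cbind(y))[, 1]
  Xd <- demean(X)
  colnames(Xd) <- colnames(X)
  scale0 <- pmax(apply(abs(X), 2, max), 1)
  absorbed <- colnames(X)[apply(abs(Xd), 2, max) < 1e-10 * scale0]
  keep <- setdiff(colnames(X), absorbed)
  Xk <- Xd[, keep, drop = FALSE]

  fit <- lm.wfit(x = Xk, y = yd, w = weights)
  dropped <- names(fit$coefficients)[is.na(fit$coefficients)]
  if (length(dropped)) {
    keep <- setdiff(keep, dropped)
    Xk <- Xd[, keep, drop = FALSE]
    fit <- lm.wfit(x = Xk, y = yd, w = weights)
    if (anyNA(fit$coefficients))
      stop_defoeval(paste("design still rank-deficient after dropping:",
                          paste(dropped, collapse = ", ")),
                    "defoeval_singular_design")
  }
  list(coefficients = fit$coefficients,
       residuals = fit$residuals,
       Xd = Xk, yd = yd,
       absorbed = absorbed, dropped = dropped,
       n_obs = n, n_cells = length(unique(cell)),
       k_params = length(fit$coefficients) + length(unique(cell)),
       weights = weights)
}

#' Cluster-robust (CR1) sandwich variance
#'
#' One-way: `B (sum_g S_g S_g') B * G/(G-1) * (N-1)/(N-K)` with
#' `B = (X'WX)^{-1}` and `S_g` the within-cluster score sums. Two-way
#' clustering uses inclusion-exclusion, `V_1 + V_2 - V_12`, each term with
#' its own CR1 correction; a non-positive-semidefinite result is repaired by
#' zeroing negative eigenvalues and flagged via the `"psd_repaired"`
#' attribute. `K` counts estimated slopes plus absorbed fixed effects.
#'
#' @param X Demeaned design matrix of the kept columns.
#' @param residuals Residual vector.
#' @param weights Observation weights.
#' @param cluster Primary cluster ids (sites).
#' @param cluster2 Optional secondary cluster ids (regions) for two-way
#'   clustering.
#' @param k_params Total parameters `K` for the small-sample factor.
#' @return Variance matrix with attributes `n_clusters` (smallest clustering
#'   dimension) and `psd_repaired`.
#' @export
cluster_robust_vcov <- function(X, residuals, weights = NULL, cluster,
                                cluster2 = NULL, k_params = ncol(X)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  bread <- solve(crossprod(X, X * weights))
  scores <- X * (weights * residuals)

  one_way <- function(cl) {
    cl <- as.character(cl)
    G <- length(unique(cl))
    if (G < 2)
      stop_defoeval("need at least two clusters", "defoeval_cluster_error")
    S <- rowsum(scores, cl)
    corr <- G / (G - 1) * (n - 1) / (n - k_params)
    list(V = corr * bread %*% crossprod(S) %*% bread, G = G)
  }

  if (is.null(cluster2)) {
    r <- one_way(cluster)
    V <- (r$V + t(r$V)) / 2
    attr(V, "n_clusters") <- r$G
    attr(V, "psd_repaired") <- FALSE
    return(V)
  }
  inter <- paste(cluster, cluster2, sep = "\r")
  r1 <- one_way(cluster); r2 <- one_way(cluster2); r12 <- one_way(inter)
  V <- r1$V + r2$V - r12$V
  V <- (V + t(V)) / 2
  repaired <- FALSE
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -1e-12 * max(abs(e$values))) {
    vals <- pmax(e$values, 0)
    V <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
    V <- (V + t(V)) / 2
    repaired <- TRUE
  }
  dimnames(V) <- dimnames(r1$V)
  attr(V, "n_clusters") <- min(r1$G, r2$G)
  attr(V, "psd_repaired") <- repaired
  V
}
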