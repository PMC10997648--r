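# Statistical matching: 1:1 nearest-neighbour matching with replacement,
# exact within vegetation zones, on a weighted generalized (Mahalanobis)
# distance whose covariate weights are tuned by a genetic algorithm to
# optimize covariate balance. Balance is summarized by standardized mean
# differences (SMD) in treated-SD units, the Love-plot statistic with the
# conventional 0.1-SD yardstick.

#' Standardized mean difference
#'
#' `(mean_T - weighted mean_C) / sd_T`, with the treated-group standard
#' deviation as the denominator (ATT convention: the treated group is fixed
#' by 1:1 with-replacement matching, so the same denominator applies before
#' and after matching). A constant treated covariate gives SMD 0 by
#' convention.
#'
#' @param treated,control Numeric vectors of covariate values.
#' @param control_weights Control reuse weights (default 1).
#' @param sd_treated Optional fixed denominator (e.g. the pre-matching
#'   treated SD when tabulating post-matching balance).
#' @return The SMD, in treated-SD units.
#' @export
standardized_mean_difference <- function(treated, control,
                                         control_weights = NULL,
                                         sd_treated = NULL) {
  if (!length(treated) || !length(control))
    stop_defoeval("empty group in SMD", "defoeval_argument_error")
  if (is.null(control_weights)) control_weights <- rep(1, length(control))
  stopifnot(length(control_weights) == length(control))
  s <- sd_treated %||% sd(treated)
  if (!is.finite(s) || s == 0) return(0)
  (mean(treated) - weighted.mean(control, control_weights)) / s
}

# Symmetric inverse square root of a covariance matrix, ridge-regularized
# if near-singular.
inv_sqrt <- function(S, ridge = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  vals <- e$values
  if (min(vals) < ridge * max(vals)) vals <- vals + ridge * max(vals)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Weighted generalized distance between covariate vectors
#'
#' `sqrt((x_i - x_j)' S^{-1/2}' W S^{-1/2} (x_i - x_j))` with `S` the
#' covariance of the standardized pooled covariates and `W` a diagonal
#' weight matrix — the distance family genetic matching searches over.
#' `W = I` recovers the Mahalanobis distance; `S = I` and `W = I` the
#' Euclidean distance.
#'
#' @param x_i,x_j Numeric covariate vectors.
#' @param scale_matrix Covariance matrix `S` (ridge-regularized if
#'   near-singular).
#' @param weights Non-negative diagonal of `W`.
#' @return The scalar distance.
#' @export
weighted_generalized_distance <- function(x_i, x_j, scale_matrix = NULL,
                                          weights = NULL) {
  k <- length(x_i)
  if (length(x_j) != k)
    stop_defoeval("dimension mismatch between x_i and x_j",
                  "defoeval_argument_error")
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(weights < 0))
    stop_defoeval("weights must be non-negative, one per covariate",
                  "defoeval_argument_error")
  if (is.null(scale_matrix)) scale_matrix <- diag(k)
  z <- inv_sqrt(scale_matrix) %*% (x_i - x_j)
  sqrt(sum(weights * z^2))
}

# Internal: prepare standardized, sphered covariate blocks per stratum.
# Returns Zt/Zc lists plus the pre-matching treated SDs used as SMD
# denominators throughout.
prep_match <- function(treated_x, control_x, strata_t, strata_c) {
  treated_x <- as.matrix(treated_x); control_x <- as.matrix(control_x)
  stopifnot(ncol(treated_x) == ncol(control_x))
  pooled <- rbind(treated_x, control_x)
  mu <- colMeans(pooled)
  sdp <- apply(pooled, 2, sd)
  sdp[sdp == 0 | !is.finite(sdp)] <- 1
  std <- sweep(sweep(pooled, 2, mu), 2, sdp, "/")
  S <- cov(std)
  R <- inv_sqrt(S)
  Z <- std %*% R
  nt <- nrow(treated_x)
  st_levels <- sort(unique(c(strata_t, strata_c)))
  bad <- vapply(st_levels, function(s)
    any(strata_t == s) && !any(strata_c == s), TRUE)
  if (any(bad))
    stop_defoeval(paste("strata with treated cells but no controls:",
                        paste(st_levels[bad], collapse = ", ")),
                  "defoeval_unmatchable_stratum")
  Zt <- Z[seq_len(nt), , drop = FALSE]
  Zc <- Z[-seq_len(nt), , drop = FALSE]
  sd_t <- apply(treated_x, 2, sd)
  sd_t[sd_t == 0 | !is.finite(sd_t)] <- Inf  # constant covariate: SMD 0
  list(Zt = Zt, Zc = Zc, Zt2 = Zt^2, Zc2 = Zc^2,
       sd_t = sd_t, mean_t = colMeans(treated_x),
       strata_t = strata_t, strata_c = strata_c,
       stratum_idx = lapply(sort(unique(strata_t)), function(s)
         list(t = which(strata_t == s), c = which(strata_c == s))),
       treated_x = treated_x, control_x = control_x)
}

# Nearest control (with replacement) per treated unit under per-covariate
# weights `w` in the sphered space; ties broken by lowest control index
# (max.col with ties.method = "first" on the negated distances).
nn_match_weights <- function(pp, w) {
  match_idx <- integer(nrow(pp$Zt))
  for (s in pp$stratum_idx) {
    a <- drop(pp$Zt2[s$t, , drop = FALSE] %*% w)
    b <- drop(pp$Zc2[s$c, , drop = FALSE] %*% w)
    D2 <- -2 * tcrossprod(pp$Zt[s$t, , drop = FALSE] * rep(w, each = length(s$t)),
                          pp$Zc[s$c, , drop = FALSE])
    D2 <- D2 + a
    D2 <- sweep(D2, 2, b, "+")
    match_idx[s$t] <- s$c[max.col(-D2, ties.method = "first")]
  }
  match_idx
}

# Post-match balance under a matching: |SMD| per covariate with reuse
# weights, denominators = pre-matching treated SDs.
post_match_smd <- function(pp, match_idx) {
  wts <- tabulate(match_idx, nbins = nrow(pp$control_x))
  wmean_c <- drop(crossprod(pp$control_x, wts)) / length(match_idx)
  (pp$mean_t - wmean_c) / pp$sd_t
}

matched_sample <- function(pp, match_idx, method, seed,
                           treated_ids = NULL, control_ids = NULL) {
  nt <- nrow(pp$Zt)
  tid <- treated_ids %||% seq_len(nt)
  cid <- control_ids %||% seq_len(nrow(pp$Zc))
  wtab <- table(match_idx)
  structure(list(
    pairs = data.frame(treated = tid, control = cid[match_idx],
                       stratum = pp$strata_t),
    control_weights = stats::setNames(as.numeric(wtab),
                                      cid[as.integer(names(wtab))]),
    method = method, seed = seed,
    smd_after = post_match_smd(pp, match_idx),
    fitness = max(abs(post_match_smd(pp, match_idx)))),
    class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("<matched_sample> %s: %d treated, %d unique controls, max|SMD| = %.3f\n",
              x$method, nrow(x$pairs), length(x$control_weights), x$fitness))
  invisible(x)
}

#' 1:1 genetic matching with replacement
#'
#' Searches, with a genetic algorithm, for the covariate weight vector whose
#' nearest-neighbour matching (with replacement, exact within strata, ties
#' to the lowest control index) best balances the covariates. Fitness is the
#' maximum post-match |SMD| across covariates (minimized) — a
#' distribution-free criterion aligned with the 0.1-SD balance yardstick.
#' The initial population always contains the equal-weight vector, and
#' elitism preserves the best candidates, so the genetic fitness never
#' exceeds that of plain Mahalanobis matching.
#'
#' @param treated_x,control_x Covariate matrices (rows = cells). The
#'   vegetation-zone stratum variable must not be a column here.
#' @param strata_t,strata_c Exact-matching stratum per row (vegetation
#'   zone); every stratum containing treated cells must contain controls.
#' @param ga_params List: `pop_size` (50), `generations` (100),
#'   `mutation_rate` (0.1), `elitism` (2), `weight_range` (c(0.1, 10),
#'   log-uniform).
#' @param seed Integer seed; the search is deterministic given it.
#' @param treated_ids,control_ids Optional external ids for the output.
#' @return A `matched_sample`: `pairs` (treated, control, stratum),
#'   `control_weights` (reuse counts, summing to the number of treated),
#'   `smd_after`, `fitness`, `method = "genetic"`, and `ga_weights`.
#' @export
genetic_match <- function(treated_x, control_x, strata_t, strata_c,
                          ga_params = list(), seed = 1L,
                          treated_ids = NULL, control_ids = NULL) {
  gp <- utils::modifyList(list(pop_size = 50L, generations = 100L,
                               mutation_rate = 0.1, elitism = 2L,
                               weight_range = c(0.1, 10)), ga_params)
  pp <- prep_match(treated_x, control_x, strata_t, strata_c)
  k <- ncol(pp$Zt)
  lo <- log(gp$weight_range[1]); hi <- log(gp$weight_range[2])

  with_seed(seed, {
    pop <- matrix(exp(runif(gp$pop_size * k, lo, hi)), gp$pop_size, k)
    pop[1, ] <- 1  # equal-weight (Mahalanobis) candidate always present
    fit <- apply(pop, 1, function(w) max(abs(post_match_smd(pp, nn_match_weights(pp, w)))))
    for (g in seq_len(gp$generations)) {
      ord <- order(fit)
      pop <- pop[ord, , drop = FALSE]; fit <- fit[ord]
      newpop <- pop
      for (i in seq(gp$elitism + 1L, gp$pop_size)) {
        # tournament selection of two parents, uniform crossover, mutation
        p1 <- min(sample.int(gp$pop_size, 2))
        p2 <- min(sample.int(gp$pop_size, 2))
        child <- ifelse(runif(k) < 0.5, pop[p1, ], pop[p2, ])
        mut <- runif(k) < gp$mutation_rate
        child[mut] <- exp(runif(sum(mut), lo, hi))
        newpop[i, ] <- child
      }
      newfit <- fit
      newfit[seq(gp$elitism + 1L, gp$pop_size)] <-
        apply(newpop[seq(gp$elitism + 1L, gp$pop_size), , drop = FALSE], 1,
              function(w) max(abs(post_match_smd(pp, nn_match_weights(pp, w)))))
      pop <- newpop; fit <- newfit
    }
    best <- pop[which.min(fit), ]
    out <- matched_sample(pp, nn_match_weights(pp, best), "genetic", seed,
                          treated_ids, control_ids)
    out$ga_weights <- best
    out
  })
}

#' Nearest-neighbour matching on Mahalanobis distance or propensity score
#'
#' The two conventional alternatives to genetic matching: 1:1 with
#' replacement within strata, on the (equal-weight) Mahalanobis distance or
#' on the estimated propensity score from a logistic regression of treatment
#' on the covariates.
#'
#' @inheritParams genetic_match
#' @param method `"mahalanobis"` or `"propensity"`.
#' @return A `matched_sample` (see [genetic_match()]); for propensity
#'   matching the fitted scores are attached as `propensity`.
#' @export
match_nearest <- function(treated_x, control_x, strata_t, strata_c,
                          method = c("mahalanobis", "propensity"), seed = 1L,
                          treated_ids = NULL, control_ids = NULL) {
  method <- match.arg(method)
  pp <- prep_match(treated_x, control_x, strata_t, strata_c)
  if (method == "mahalanobis") {
    out <- matched_sample(pp, nn_match_weights(pp, rep(1, ncol(pp$Zt))),
                          "mahalanobis", seed, treated_ids, control_ids)
    return(out)
  }
  y <- c(rep(1L, nrow(pp$treated_x)), rep(0L, nrow(pp$control_x)))
  X <- rbind(pp$treated_x, pp$control_x)
  fit <- tryCatch(
    glm(y ~ X, family = binomial(), control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop_defoeval("propensity model separation: fit did not stabilize",
                      "defoeval_propensity_error")
      suppressWarnings(glm(y ~ X, family = binomial(), control = list(maxit = 100)))
    })
  if (!fit$converged)
    stop_defoeval("propensity model did not converge in 100 iterations",
                  "defoeval_propensity_error")
  score <- fit$fitted.values
  st <- score[seq_len(nrow(pp$treated_x))]
  sc <- score[-seq_len(nrow(pp$treated_x))]
  match_idx <- integer(length(st))
  for (s in unique(pp$strata_t)) {
    it <- which(pp$strata_t == s); ic <- which(pp$strata_c == s)
    D <- round(abs(outer(st[it], sc[ic], "-")), 12)
    match_idx[it] <- ic[max.col(-D, ties.method = "first")]
  }
  out <- matched_sample(pp, match_idx, "propensity", seed,
                        treated_ids, control_ids)
  out$propensity <- list(coefficients = coef(fit), treated = st, control = sc)
  out
}

#' Covariate balance before and after matching
#'
#' Per-covariate SMDs comparing the treated group against the full control
#' pool (before, unweighted) and against the matched controls (after,
#' reuse-weighted), both in pre-matching treated-SD units — the numbers a
#' Love plot displays against the 0.1-SD balance line.
#'
#' @param treated_x,control_x Covariate matrices of the pre-matching sample.
#' @param matched A `matched_sample` from [genetic_match()] or
#'   [match_nearest()] (or `NULL` for a before-only table). Its `pairs$control`
#'   must index rows of `control_x` (the default when ids were not remapped).
#' @return Data frame: `covariate`, `smd_before`, `smd_after`.
#' @export
balance_table <- function(treated_x, control_x, matched = NULL) {
  treated_x <- as.matrix(treated_x); control_x <- as.matrix(control_x)
  stopifnot(ncol(treated_x) == ncol(control_x))
  nm <- colnames(treated_x) %||% paste0("x", seq_len(ncol(treated_x)))
  sd_t <- apply(treated_x, 2, sd)
  before <- vapply(seq_len(ncol(treated_x)), function(j)
    standardized_mean_difference(treated_x[, j], control_x[, j],
                                 sd_treated = sd_t[j]), 0.0)
  after <- rep(NA_real_, length(before))
  if (!is.null(matched)) {
    wtab <- table(matched$pairs$control)
    uc <- as.integer(names(wtab))
    after <- vapply(seq_len(ncol(treated_x)), function(j)
      standardized_mean_difference(treated_x[, j], control_x[uc, j],
                                   as.numeric(wtab), sd_treated = sd_t[j]), 0.0)
  }
  data.frame(covariate = nm, smd_before = before, smd_after = after)
}
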