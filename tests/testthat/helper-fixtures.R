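# Shared fixtures and independent oracles, all built in code.

# Small landscape for fast tests: ~500 analysis cells, 12 sites.
tiny_config <- function(seed = 1L, ...) {
  sim_config(grid_rows = 90, grid_cols = 63,
             n_cfm_units = 8, n_mnp_units = 4,
             cfm_unit_dim = c(12, 12), mnp_unit_dim = c(15, 18),
             seed = seed, ...)
}

# A single-cell cover series from a vector of percentages.
cover1 <- function(values, years = seq(2000, by = 1,
                                       length.out = length(values)),
                   resolution = 90) {
  forest_cover_series(array(values, c(1, 1, length(values))), years,
                      resolution)
}

# Random monotone (no-regrowth) cover series.
random_cover <- function(nr, nc, ny, resolution = 90, seed = 1) {
  set.seed(seed)
  cov <- array(0, c(nr, nc, ny))
  cur <- matrix(runif(nr * nc, 0, 100), nr, nc)
  for (k in seq_len(ny)) {
    cov[, , k] <- cur
    cur <- cur * matrix(runif(nr * nc, 0.7, 1), nr, nc)
  }
  forest_cover_series(cov, 2000 + seq_len(ny) - 1, resolution)
}

# O(n^2) all-pairs nearest-neighbor oracle for the edge distance.
bf_edge_distance <- function(forest, resolution) {
  nr <- nrow(forest); nc <- ncol(forest)
  nf <- which(!forest, arr.ind = TRUE)
  if (nrow(nf) == 0)
    return(matrix(sqrt((nr * resolution)^2 + (nc * resolution)^2), nr, nc))
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (forest[i, j])
      out[i, j] <- sqrt(min((nf[, 1] - i)^2 + (nf[, 2] - j)^2)) * resolution
  }
  out
}

# Brute-force block mean oracle.
bf_block_mean <- function(m, f) {
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- mean(m[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  out
}

# Hand-built management map on an nr x nc analysis grid: left half CFM unit
# 1, right half MNP unit 2, with optional overlap cells.
toy_management <- function(nr = 6, nc = 6, overlap_cells = NULL,
                           renewed = TRUE, established = c(2000, 1995)) {
  uid <- matrix(NA_integer_, nr, nc)
  uid[, seq_len(nc %/% 2)] <- 1L
  uid[, (nc %/% 2 + 1):nc] <- 2L
  ov <- matrix(FALSE, nr, nc)
  if (!is.null(overlap_cells)) {
    ov[overlap_cells] <- TRUE
    uid[overlap_cells] <- NA_integer_
  }
  units <- data.frame(unit_id = 1:2, kind = c("CFM", "MNP"),
                      established_year = established,
                      renewed = c(renewed, FALSE),
                      vegetation_zone = c(1L, 1L), region_id = c(1L, 2L))
  management_map(uid, units, ov)
}

# Independent damped-Newton logistic regression oracle.
bf_logit_newton <- function(X, y, tol = 1e-10, max_iter = 200) {
  X <- cbind(1, X)
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    p <- 1 / (1 + exp(-eta))
    g <- crossprod(X, y - p)
    if (max(abs(g)) < tol) break
    W <- p * (1 - p)
    H <- crossprod(X, X * W)
    step <- solve(H, g)
    # damping: halve until the log-likelihood does not decrease
    ll <- function(bb) {
      e <- as.vector(X %*% bb)
      sum(y * e - log1p(exp(e)))
    }
    lam <- 1
    while (ll(b + lam * step) < ll(b) && lam > 1e-8) lam <- lam / 2
    b <- b + lam * step
  }
  as.vector(b)
}

# Direct dense dummy-variable OLS oracle (normal equations).
bf_dummy_ols <- function(y, X, cell, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  D <- outer(cell, sort(unique(cell)), "==") * 1
  Z <- cbind(X, D)
  W <- diag(weights)
  beta <- solve(t(Z) %*% W %*% Z, t(Z) %*% W %*% y)
  beta[seq_len(ncol(X))]
}

# Direct CR1 sandwich oracle by explicit block sums.
bf_cluster_vcov <- function(X, e, w, cl, k_params) {
  n <- nrow(X)
  B <- solve(t(X) %*% (X * w))
  gs <- unique(cl)
  M <- matrix(0, ncol(X), ncol(X))
  for (g in gs) {
    i <- which(cl == g)
    s <- colSums(X[i, , drop = FALSE] * (w[i] * e[i]))
    M <- M + outer(s, s)
  }
  G <- length(gs)
  G / (G - 1) * (n - 1) / (n - k_params) * B %*% M %*% B
}

# Confounded matching fixture: treated shifted on some covariates, with a
# shared stratum structure.
confounded_match_fixture <- function(n_t = 120, n_c = 240, seed = 1) {
  set.seed(seed)
  k <- 5
  xc <- matrix(rnorm(n_c * k), n_c, k)
  xt <- matrix(rnorm(n_t * k), n_t, k)
  xt[, 1] <- xt[, 1] + 0.9   # strong confounder
  xt[, 2] <- xt[, 2] + 0.5
  colnames(xt) <- colnames(xc) <- paste0("x", 1:k)
  list(xt = xt, xc = xc,
       st = sample(1:2, n_t, replace = TRUE),
       sc = sample(1:2, n_c, replace = TRUE))
}

fast_ga <- list(pop_size = 20L, generations = 25L)

# Pre-match covariate balance between CFM and MNP cells of a scenario.
premat_smd <- function(scen) {
  f <- scen$truth$analysis_factor
  cov_a <- aggregate_cover(scen$cover, f)
  mgmt <- defoeval:::aggregate_management(scen$management, f)
  tr <- eligible_cells(mgmt, cov_a, 2005, kinds = "CFM")
  ct <- eligible_cells(mgmt, cov_a, 2005, kinds = "MNP")
  xt <- defoeval:::static_covariate_table(scen, cov_a, tr)
  xc <- defoeval:::static_covariate_table(scen, cov_a, ct)
  setNames(balance_table(xt, xc)$smd_before, colnames(xt))
}

# Balance-diagnostic fixture: many smaller units and a shorter field
# correlation length, so per-seed SMD noise (driven by the number of units,
# not of cells) is small enough for a 20-seed Monte Carlo to resolve the
# assignment-mechanism properties.
balance_config <- function(seed, scale) {
  sim_config(grid_rows = 240, grid_cols = 162,
             n_cfm_units = 40, n_mnp_units = 20,
             cfm_unit_dim = c(15, 15), mnp_unit_dim = c(21, 24),
             spatial_correlation_length = 150,
             confounding_scale = scale, hazard_confounding = 0, seed = seed)
}

score_covariates <- c("dist_road", "dist_village", "dist_cart_track",
                      "popdens_2005", "elevation", "slope")
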