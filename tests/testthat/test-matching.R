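test_that("SMD matches hand arithmetic and its invariances", {
  expect_equal(standardized_mean_difference(c(2, 4), c(1, 3)),
               1 / sqrt(2), tolerance = 1e-12)
  expect_equal(standardized_mean_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  # affine transform of both groups leaves |SMD| unchanged
  t0 <- rnorm(20); c0 <- rnorm(30)
  s0 <- standardized_mean_difference(t0, c0)
  expect_equal(abs(standardized_mean_difference(3 * t0 - 7, 3 * c0 - 7)),
               abs(s0), tolerance = 1e-10)
  # constant treated covariate: SMD defined as 0
  expect_equal(standardized_mean_difference(rep(2, 5), c(1, 3)), 0)
  expect_error(standardized_mean_difference(numeric(), 1:3),
               class = "defoeval_argument_error")
})

test_that("the weighted generalized distance nests its special cases", {
  x <- c(1, 2, 3); y <- c(0, 1, 5)
  expect_equal(weighted_generalized_distance(x, x), 0)
  expect_equal(weighted_generalized_distance(x, y, diag(3), rep(1, 3)),
               sqrt(sum((x - y)^2)), tolerance = 1e-12)
  set.seed(2)
  A <- matrix(rnorm(25), 5, 5); S <- crossprod(A) + diag(5)
  xi <- rnorm(5); xj <- rnorm(5)
  maha <- sqrt(drop(t(xi - xj) %*% solve(S) %*% (xi - xj)))
  expect_equal(weighted_generalized_distance(xi, xj, S, rep(1, 5)), maha,
               tolerance = 1e-10)
  expect_error(weighted_generalized_distance(1:2, 1:3),
               class = "defoeval_argument_error")
})

test_that("perfect twins give zero fitness and identical pairs", {
  set.seed(4)
  xt <- matrix(rnorm(40), 20, 2)
  xc <- rbind(xt, matrix(rnorm(60), 30, 2))
  st <- rep(1:2, 10); sc <- c(st, rep(1:2, 15))
  m <- genetic_match(xt, xc, st, sc, fast_ga, seed = 1)
  expect_equal(m$fitness, 0, tolerance = 1e-12)
  expect_equal(m$pairs$control, seq_len(20))
})

test_that("no pairing crosses vegetation-zone strata, any method", {
  fx <- confounded_match_fixture(seed = 11)
  for (m in list(genetic_match(fx$xt, fx$xc, fx$st, fx$sc, fast_ga, seed = 2),
                 match_nearest(fx$xt, fx$xc, fx$st, fx$sc, "mahalanobis"),
                 match_nearest(fx$xt, fx$xc, fx$st, fx$sc, "propensity"))) {
    expect_true(all(fx$sc[m$pairs$control] == fx$st))
    # ATT bookkeeping: reuse weights sum to the number of treated
    expect_equal(sum(m$control_weights), nrow(fx$xt))
  }
  expect_error(genetic_match(fx$xt, fx$xc, fx$st, rep(2, nrow(fx$xc)),
                             fast_ga, seed = 1),
               class = "defoeval_unmatchable_stratum")
})

test_that("genetic search never loses to equal weights and beats a grid", {
  # covariate A is the sole confounder on a small two-covariate instance
  set.seed(21)
  xt <- cbind(A = rnorm(30) + 1.2, B = rnorm(30))
  xc <- cbind(A = rnorm(60), B = rnorm(60))
  st <- rep(1L, 30); sc <- rep(1L, 60)
  equal <- match_nearest(xt, xc, st, sc, "mahalanobis")
  ga <- genetic_match(xt, xc, st, sc,
                      list(pop_size = 30L, generations = 40L), seed = 3)
  expect_lte(ga$fitness, equal$fitness + 1e-12)

  # exhaustive 100-point weight grid oracle over the same distance family
  grid <- expand.grid(wA = exp(seq(log(0.1), log(10), length.out = 10)),
                      wB = exp(seq(log(0.1), log(10), length.out = 10)))
  pp <- defoeval:::prep_match(xt, xc, st, sc)
  grid_fit <- apply(grid, 1, function(w) {
    max(abs(defoeval:::post_match_smd(pp, defoeval:::nn_match_weights(pp, w))))
  })
  expect_lte(ga$fitness, min(grid_fit) + 1e-9)
})

test_that("GA dominance over Mahalanobis holds across random fixtures", {
  for (s in 1:5) {
    fx <- confounded_match_fixture(n_t = 60, n_c = 120, seed = 30 + s)
    ga <- genetic_match(fx$xt, fx$xc, fx$st, fx$sc, fast_ga, seed = s)
    eq <- match_nearest(fx$xt, fx$xc, fx$st, fx$sc, "mahalanobis")
    expect_lte(ga$fitness, eq$fitness + 1e-12)
  }
})

test_that("single-covariate nearest matching picks the nearest value", {
  xt <- cbind(v = c(1.0, 3.9))
  xc <- cbind(v = c(0.0, 1.2, 4.5))
  m <- match_nearest(xt, xc, c(1, 1), c(1, 1, 1), "mahalanobis")
  expect_equal(m$pairs$control, c(2, 3))
})

test_that("propensity coefficients agree with a damped-Newton oracle", {
  set.seed(8)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  xt <- X[y == 1, , drop = FALSE]; xc <- X[y == 0, , drop = FALSE]
  m <- match_nearest(xt, xc, rep(1, nrow(xt)), rep(1, nrow(xc)), "propensity")
  oracle <- bf_logit_newton(rbind(xt, xc),
                            c(rep(1, nrow(xt)), rep(0, nrow(xc))))
  expect_equal(unname(m$propensity$coefficients), oracle, tolerance = 1e-6)
})

test_that("a separable treatment indicator raises a propensity-fit error", {
  xt <- cbind(v = seq(2, 3, length.out = 15))
  xc <- cbind(v = seq(-3, -2, length.out = 20))
  expect_error(match_nearest(xt, xc, rep(1, 15), rep(1, 20), "propensity"),
               class = "defoeval_propensity_error")
})

test_that("propensity matching on an unconfounded fixture stays valid", {
  set.seed(12)
  xt <- matrix(rnorm(60), 30, 2); xc <- matrix(rnorm(80), 40, 2)
  st <- rep(1L, 30); sc <- rep(1L, 40)
  m <- match_nearest(xt, xc, st, sc, "propensity")
  expect_equal(nrow(m$pairs), 30)
  expect_true(all(m$pairs$control %in% seq_len(40)))
  expect_equal(sum(m$control_weights), 30)
  # scores nearly constant: spread far smaller than under real confounding
  expect_lt(sd(c(m$propensity$treated, m$propensity$control)), 0.2)
})

test_that("balance tables behave at the edges and improve under matching", {
  set.seed(5)
  xt <- matrix(rnorm(40), 20, 2)
  xc <- rbind(xt, matrix(rnorm(40) + 2, 20, 2))
  colnames(xt) <- colnames(xc) <- c("a", "b")
  twins <- genetic_match(xt, xc, rep(1, 20), rep(1, 40), fast_ga, seed = 1)
  bal <- balance_table(xt, xc, twins)
  expect_equal(bal$smd_after, c(0, 0), tolerance = 1e-12)

  # a bijective matching reproduces the before column exactly
  ident <- structure(list(pairs = data.frame(treated = 1:20, control = 1:20)),
                     class = "matched_sample")
  bal2 <- balance_table(xt, xt, ident)
  expect_equal(bal2$smd_before, bal2$smd_after, tolerance = 1e-12)

  fx <- confounded_match_fixture(seed = 44)
  colnames(fx$xt) <- colnames(fx$xc) <- paste0("x", 1:5)
  ga <- genetic_match(fx$xt, fx$xc, fx$st, fx$sc, fast_ga, seed = 9)
  bal3 <- balance_table(fx$xt, fx$xc, ga)
  expect_lt(max(abs(bal3$smd_after)), max(abs(bal3$smd_before)))
})
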