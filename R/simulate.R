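# Synthetic landscape generator: spatially autocorrelated confounders,
# accessibility-driven assignment of management units, and an absorbing
# forest-loss hazard with configurable yearly treatment effects. The
# generator is first-class, tested code: its defaults define the study
# conditions under which the estimators are validated.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic landscape. The defaults emulate the
#' study conditions of the Madagascar evaluation: a 2000-2020 annual cover
#' series, three vegetation zones, community-managed (CFM) units placed
#' preferentially in accessible cells and state protected (MNP) units in
#' remote high-elevation cells, pre-crisis background deforestation around
#' 0.2-0.7 %/yr rising through the 2010-2014 crisis and 2015-2020 post-crisis
#' windows, and yearly CFM effects in 2014-2017 of 1.7-2.4 percentage points.
#'
#' `delta_true` is the ground-truth yearly CFM effect on annual deforestation
#' expressed as an additive probability (fraction of cell area at the
#' analysis resolution, e.g. 0.02 = 2 percentage points of extra loss per
#' year). `year_shocks` are common log-odds shifts shared by all cells.
#' `confounding_strengths` weight standardized covariates in the assignment
#' score; `confounding_scale` rescales them all at once.
#'
#' @param grid_rows,grid_cols Base-resolution (30 m) grid size.
#' @param first_year First cover year.
#' @param n_years_cover Number of annual cover layers.
#' @param n_cfm_units,n_mnp_units Number of management units per kind.
#' @param cfm_unit_dim,mnp_unit_dim Unit footprint (rows, cols) in base
#'   cells; MNP units are larger, mirroring real protected areas.
#' @param vegetation_zone_count Number of contiguous vegetation-zone bands.
#' @param n_regions Number of administrative regions (second cluster level).
#' @param confounding_strengths Named covariate weights in the assignment
#'   score.
#' @param confounding_scale Scalar multiplier applied to all strengths.
#' @param mnp_remoteness Relative sharpness of MNP placement toward remote
#'   cells (1 = as sharp as CFM's pull toward accessible cells; the default
#'   0.4 keeps common support between the arms, as large parks span
#'   accessibility gradients).
#' @param placement_jitter SD (in units of the score's SD) of the
#'   unobserved cell-level component of unit placement: drivers of siting
#'   outside the measured covariates. Keeps the covariate distributions of
#'   the two arms overlapping despite mean differences, a prerequisite for
#'   matching with replacement to have controls to reuse.
#' @param hazard_intercept Log-odds of annual clearing for an average cell.
#' @param hazard_confounding Loading of the assignment score on the cell
#'   effect (creates real confounding for matching/fixed effects to remove).
#' @param cell_effect_sd SD of the idiosyncratic per-cell hazard effect.
#' @param psi_true Named true coefficients of time-variant covariates in the
#'   hazard (log-odds scale; `dist_forest_edge` is taken in km).
#' @param delta_true Named (by year) true CFM effects, probability scale.
#' @param pretrend_cfm Differential linear CFM pre-trend, in percentage
#'   points per year of extra annual deforestation (0 = parallel trends).
#' @param effect_moderator Optional name of a static covariate `m`; if set,
#'   yearly effects become `delta_true * (1 + z(m))` cell by cell.
#' @param year_shocks Named (by year) common log-odds shocks.
#' @param crisis_years,post_years Crisis calendar (defaults 2010-2014 and
#'   2015-2020; pre-crisis is everything before).
#' @param spatial_correlation_length Gaussian smoothing bandwidth in meters
#'   for the confounder fields.
#' @param forest_init_fraction Fraction of cells forested in the first year.
#' @param analysis_factor Block size (in base cells) of the analysis
#'   resolution at which `delta_true` is defined (3 = 90 m).
#' @param renewed_prob Probability a CFM unit's contract is flagged renewed.
#' @param seed Integer seed; fully determines all outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_rows = 270, grid_cols = 180,
                       first_year = 2000, n_years_cover = 21,
                       n_cfm_units = 24, n_mnp_units = 12,
                       cfm_unit_dim = c(21, 21), mnp_unit_dim = c(30, 36),
                       vegetation_zone_count = 3, n_regions = 6,
                       confounding_strengths = c(dist_road = -0.8,
                                                 dist_village = -0.6,
                                                 dist_cart_track = -0.5,
                                                 popdens_2005 = 0.6,
                                                 elevation = -0.5,
                                                 slope = -0.3),
                       confounding_scale = 1,
                       mnp_remoteness = 0.4,
                       placement_jitter = 1,
                       hazard_intercept = qlogis(0.0045),
                       hazard_confounding = 0.45,
                       cell_effect_sd = 0.45,
                       psi_true = c(dist_forest_edge = -0.25,
                                    drought_pdsi = -0.08,
                                    max_precip = 0.004),
                       delta_true = c("2014" = 0.0179, "2015" = 0.0170,
                                      "2016" = 0.0175, "2017" = 0.0243),
                       pretrend_cfm = 0,
                       effect_moderator = NULL,
                       year_shocks = c(stats::setNames(rep(0.55, 5), 2010:2014),
                                       stats::setNames(rep(1.0, 6), 2015:2020)),
                       crisis_years = 2010:2014, post_years = 2015:2020,
                       spatial_correlation_length = 300,
                       forest_init_fraction = 0.88,
                       analysis_factor = 3,
                       renewed_prob = 0.5,
                       seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              first_year = as.integer(first_year),
              n_years_cover = as.integer(n_years_cover),
              n_cfm_units = as.integer(n_cfm_units),
              n_mnp_units = as.integer(n_mnp_units),
              cfm_unit_dim = as.integer(cfm_unit_dim),
              mnp_unit_dim = as.integer(mnp_unit_dim),
              vegetation_zone_count = as.integer(vegetation_zone_count),
              n_regions = as.integer(n_regions),
              confounding_strengths = confounding_strengths * confounding_scale,
              confounding_scale = confounding_scale,
              mnp_remoteness = mnp_remoteness,
              placement_jitter = placement_jitter,
              hazard_intercept = hazard_intercept,
              hazard_confounding = hazard_confounding,
              cell_effect_sd = cell_effect_sd,
              psi_true = psi_true,
              delta_true = delta_true,
              pretrend_cfm = pretrend_cfm,
              effect_moderator = effect_moderator,
              year_shocks = year_shocks,
              crisis_years = as.integer(crisis_years),
              post_years = as.integer(post_years),
              spatial_correlation_length = spatial_correlation_length,
              forest_init_fraction = forest_init_fraction,
              analysis_factor = as.integer(analysis_factor),
              renewed_prob = renewed_prob,
              seed = as.integer(seed))
  with(cfg, stopifnot(grid_rows > 0, grid_cols > 0, n_years_cover > 1,
                      n_cfm_units > 0, n_mnp_units > 0,
                      vegetation_zone_count > 0, analysis_factor >= 1))
  yrs <- cfg$first_year:(cfg$first_year + cfg$n_years_cover - 1L)
  if (length(cfg$delta_true) &&
      !all(as.integer(names(cfg$delta_true)) %in% yrs))
    stop_defoeval("delta_true years must lie within the cover years",
                  "defoeval_argument_error")
  cfg$cover_years <- yrs
  class(cfg) <- "sim_config"
  cfg
}

#' True yearly effect schedule
#'
#' Expands the configured `delta_true` map to a complete year-by-year
#' schedule over the cover years (zero where unconfigured). This is the
#' ground truth the Monte Carlo recovery experiments compare estimates
#' against.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector, one entry per cover year.
#' @export
true_effect_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sched <- stats::setNames(rep(0, length(config$cover_years)),
                           config$cover_years)
  if (length(config$delta_true))
    sched[names(config$delta_true)] <- config$delta_true
  sched
}

# Spatially autocorrelated standard-normal-ish field: white noise smoothed
# with a separable Gaussian kernel (bandwidth = correlation length), then
# re-standardized. Edge effects handled by kernel-mass normalization.
gauss_field <- function(nr, nc, bw_cells) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (bw_cells <= 0) return(z)
  K <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / bw_cells)^2)
    k[d > 3 * bw_cells] <- 0
    k / rowSums(k)
  }
  f <- K(nr) %*% z %*% t(K(nc))
  (f - mean(f)) / sd(f)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Generate a complete synthetic scenario
#'
#' Builds, from a single seed: spatially autocorrelated static confounders
#' (the standard matching covariates: rice suitability, elevation, slope,
#' precipitation, distances to village/urban center/road/cart track,
#' population density), contiguous vegetation-zone bands, rectangular CFM
#' and MNP management units placed with accessibility-confounded assignment
#' (CFM in accessible cells, MNP in remote high-elevation cells), national
#' rice-price series, cell-year climate covariates, and an annual binary
#' forest-cover series driven by the configured hazard. Where a CFM
#' candidate footprint intersects an existing MNP unit, the intersection
#' cells are flagged as overlapping designations (claimed by both kinds) and
#' assigned to neither, so the downstream overlap-exclusion rule has real
#' work to do.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_scenario` list with elements `cover`
#'   ([forest_cover_series()], binary base resolution), `management`
#'   (unit map + unit table), `static` (named list of covariate matrices),
#'   `time_variant` (cell-year arrays + national series), `cell_effect`,
#'   `assignment_score`, and `truth` (the config).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nr <- config$grid_rows; nc <- config$grid_cols
    bw <- config$spatial_correlation_length / 30
    f <- function() gauss_field(nr, nc, bw)

    elevation <- 600 + 400 * f()
    slope <- pmax(12 + 8 * f() + 0.004 * (elevation - 600), 0)
    precipitation <- pmax(1400 + 450 * f() - 0.25 * (elevation - 600), 300)
    dist_road <- exp(6.5 + 1.0 * f())
    dist_village <- exp(6.8 + 0.9 * f())
    dist_urban <- exp(9.5 + 0.7 * f())
    dist_cart_track <- exp(6.0 + 1.0 * f())
    popdens_2005 <- exp(2.5 - 0.8 * zscore(log(dist_village)) + 0.6 * f())
    rs_field <- f() + 0.3 * zscore(precipitation)
    rice_suitability <- (rs_field > stats::quantile(rs_field, 0.7)) * 1

    static <- list(rice_suitability = rice_suitability, elevation = elevation,
                   slope = slope, precipitation = precipitation,
                   dist_village = dist_village, dist_urban = dist_urban,
                   dist_road = dist_road, dist_cart_track = dist_cart_track,
                   popdens_2005 = popdens_2005)

    # assignment score: accessible (low distances, high density) cells score
    # high; CFM centers drawn with weight exp(+score), MNP with exp(-score)
    score <- matrix(0, nr, nc)
    for (nm in names(config$confounding_strengths)) {
      if (!nm %in% names(static))
        stop_defoeval(sprintf("unknown covariate '%s' in confounding_strengths", nm),
                      "defoeval_argument_error")
      score <- score + config$confounding_strengths[[nm]] * zscore(static[[nm]])
    }

    zones <- matrix(rep(ceiling(seq_len(nc) / (nc / config$vegetation_zone_count)),
                        each = nr), nr, nc)
    zones[zones > config$vegetation_zone_count] <- config$vegetation_zone_count
    reg_cols <- max(1L, min(3L, config$n_regions))
    reg_rows <- max(1L, ceiling(config$n_regions / reg_cols))
    regions <- (matrix(rep(pmin(reg_rows, ceiling(seq_len(nr) / (nr / reg_rows))),
                           nc), nr, nc) - 1) * reg_cols +
      matrix(rep(pmin(reg_cols, ceiling(seq_len(nc) / (nc / reg_cols))),
                 each = nr), nr, nc)

    mgmt <- place_units(config, score, zones)
    unit_id <- mgmt$unit_id; overlap <- mgmt$overlap; units <- mgmt$units
    ctr <- cbind(units$center_row, units$center_col)
    units$vegetation_zone <- zones[ctr]
    units$region_id <- regions[ctr]
    units$renewed <- ifelse(units$kind == "CFM",
                            runif(nrow(units)) < config$renewed_prob, FALSE)
    management <- management_map(unit_id, units, overlap,
                                 vegetation_zone = zones, region = regions)

    time_variant <- simulate_time_variant(config, static)
    cell_effect <- config$hazard_confounding * zscore(score) +
      rnorm(nr * nc, sd = config$cell_effect_sd)
    cell_effect <- matrix(cell_effect, nr, nc)

    init_field <- f()
    init_forest <- init_field > stats::quantile(init_field,
                                                1 - config$forest_init_fraction)

    scen <- list(management = management, static = static,
                 time_variant = time_variant, cell_effect = cell_effect,
                 assignment_score = score, init_forest = init_forest,
                 truth = config)
    scen$cover <- simulate_forest_dynamics(scen, config,
                                           seed = derive_seed(config$seed, "dynamics"))
    class(scen) <- "synthetic_scenario"
    scen
  })
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  u <- x$management$units
  cat(sprintf("<synthetic_scenario> %d x %d base cells, years %d-%d\n",
              x$truth$grid_rows, x$truth$grid_cols,
              min(x$truth$cover_years), max(x$truth$cover_years)))
  cat(sprintf("  units: %d CFM, %d MNP; overlap cells: %d\n",
              sum(u$kind == "CFM"), sum(u$kind == "MNP"),
              sum(x$management$overlap)))
  invisible(x)
}

# Rectangular unit placement. MNP first (remote, high score weight on
# -score, rotating across vegetation zones so every zone holds comparison
# area, as the real park system does), then CFM (accessible). CFM
# rectangles may clip into MNP footprints: the intersection becomes overlap
# (both-kind claim, assigned to neither unit), capped at 25% of the
# candidate's area.
place_units <- function(config, score, zones) {
  nr <- nrow(score); nc <- ncol(score)
  unit_id <- matrix(NA_integer_, nr, nc)
  overlap <- matrix(FALSE, nr, nc)
  units <- list()
  next_id <- 1L

  place_kind <- function(kind, n, dims, w, zone_cycle = FALSE) {
    rd <- dims[1]; cd <- dims[2]
    if (rd > nr || cd > nc)
      stop_defoeval("grid too small for requested unit size",
                    "defoeval_sizing_error")
    ok <- matrix(FALSE, nr, nc)
    ok[seq_len(nr - rd + 1), seq_len(nc - cd + 1)] <- TRUE
    zone_ids <- if (zone_cycle) sort(unique(as.vector(zones))) else 0L
    masks <- lapply(zone_ids, function(z) {
      if (z == 0L) return(ok)
      # whole footprint inside the zone band (zones are column bands), so
      # units cycled into one zone cannot crowd out a neighbouring zone
      zcol <- zones[1, ]
      in_band <- zcol == z &
        zcol[pmin(seq_len(nc) + cd - 1L, nc)] == z
      ok & matrix(in_band, nr, nc, byrow = TRUE)
    })
    cws <- lapply(masks, function(m) cumsum(as.vector(exp(pmin(w, 8)) * m)))
    cus <- lapply(masks, function(m) cumsum(as.vector(m * 1)))
    draw_center <- function(cum) {
      if (cum[length(cum)] == 0) return(NULL)
      idx <- findInterval(runif(1) * cum[length(cum)], cum) + 1L
      c((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
    }
    af <- config$analysis_factor

    # attempt a unit with its snapped corner at `ctr`; TRUE if placed
    try_place <- function(kind, ctr, rd, cd) {
      ctr <- pmin(1L + af * ((ctr - 1L) %/% af),
                  c(nr - rd + 1L, nc - cd + 1L))
      rows <- ctr[1]:(ctr[1] + rd - 1); cols <- ctr[2]:(ctr[2] + cd - 1)
      patch <- unit_id[rows, cols]
      if (kind == "MNP") {
        if (any(!is.na(patch) | overlap[rows, cols])) return(FALSE)
        unit_id[rows, cols] <<- next_id
      } else {
        taken_kind <- matrix("", rd, cd)
        taken_kind[!is.na(patch)] <-
          vapply(patch[!is.na(patch)], function(id) units[[id]]$kind, "")
        if (any(taken_kind == "CFM") || any(overlap[rows, cols]))
          return(FALSE)
        if (sum(taken_kind == "MNP") > 0.25 * rd * cd) return(FALSE)
        ov <- !is.na(patch)
        blk_u <- unit_id[rows, cols]
        blk_o <- overlap[rows, cols]
        blk_o[ov] <- TRUE
        blk_u[!ov] <- next_id
        blk_u[ov] <- NA_integer_
        unit_id[rows, cols] <<- blk_u
        overlap[rows, cols] <<- blk_o
      }
      units[[next_id]] <<- list(unit_id = next_id, kind = kind,
                                center_row = ctr[1] + rd %/% 2,
                                center_col = ctr[2] + cd %/% 2)
      next_id <<- next_id + 1L
      TRUE
    }

    for (i in seq_len(n)) {
      zi <- (i - 1L) %% length(zone_ids) + 1L
      placed <- FALSE
      for (try in seq_len(800)) {
        # weighted draws first; if the high-weight region is saturated,
        # fall back to uniform draws over feasible corners. Corners are
        # snapped to the analysis-cell lattice so unit boundaries do not
        # split analysis blocks (the configured effect then applies to
        # whole analysis cells, undiluted).
        ctr <- draw_center(if (try <= 400) cws[[zi]] else cus[[zi]])
        if (is.null(ctr)) break
        if (try_place(kind, ctr, rd, cd)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # last resort: deterministic scan of the feasible lattice corners
        cand <- which(as.vector(masks[[zi]]))
        cand <- cand[((cand - 1) %% nr) %% af == 0 &
                       ((cand - 1) %/% nr) %% af == 0]
        for (idx in cand) {
          ctr <- c((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
          if (try_place(kind, ctr, rd, cd)) {
            placed <- TRUE
            break
          }
        }
      }
      if (!placed)
        stop_defoeval(sprintf("grid too small to place %d %s units", n, kind),
                      "defoeval_sizing_error")
    }
  }

  # the raw score, not a standardized version: its magnitude is what the
  # confounding scale controls; MNP selection is less sharp than CFM's
  # (large parks span accessibility gradients), and an unobserved jitter
  # component reflects placement drivers outside the measured covariates —
  # both keep common support between the arms, as in the real landscape
  jit <- function() config$placement_jitter * sd(score) *
    matrix(rnorm(nr * nc), nr, nc)
  place_kind("MNP", config$n_mnp_units, config$mnp_unit_dim,
             -config$mnp_remoteness * score + jit(), zone_cycle = TRUE)
  place_kind("CFM", config$n_cfm_units, config$cfm_unit_dim, score + jit())

  est <- function(kind) if (kind == "CFM") sample(1999:2004, 1)
         else sample(1985:2003, 1)
  tab <- do.call(rbind, lapply(units, function(u)
    data.frame(unit_id = u$unit_id, kind = u$kind,
               center_row = u$center_row, center_col = u$center_col)))
  tab$established_year <- vapply(tab$kind, est, 0)
  list(unit_id = unit_id, overlap = overlap, units = tab)
}

# Cell-year time-variant covariates plus national rice-price series. Climate
# covariates combine a national annual anomaly, a static spatial sensitivity
# field interacted with a second anomaly, and idiosyncratic cell-year noise,
# giving genuine within-cell variation for the panel regression to use.
simulate_time_variant <- function(config, static) {
  nr <- config$grid_rows; nc <- config$grid_cols
  yrs <- config$cover_years; ny <- length(yrs)
  bw <- config$spatial_correlation_length / 30

  climate <- function(level, nat_sd, amp, noise_sd, clip = NULL) {
    sens <- gauss_field(nr, nc, bw)
    nat <- rnorm(ny, 0, nat_sd)
    mod <- rnorm(ny, 0, 1)
    arr <- array(0, c(nr, nc, ny))
    for (k in seq_len(ny)) {
      arr[, , k] <- level + nat[k] + amp * sens * mod[k] +
        rnorm(nr * nc, sd = noise_sd)
    }
    if (!is.null(clip)) arr <- pmin(pmax(arr, clip[1]), clip[2])
    dimnames(arr) <- list(NULL, NULL, yrs)
    arr
  }

  popdens <- array(0, c(nr, nc, ny))
  growth <- cumprod(c(1, exp(rnorm(ny - 1, 0.015, 0.004))))
  for (k in seq_len(ny)) popdens[, , k] <- static$popdens_2005 * growth[k]
  dimnames(popdens) <- list(NULL, NULL, yrs)

  price <- numeric(ny)
  price[1] <- 800
  for (k in seq_len(ny - 1))
    price[k + 1] <- price[k] * exp(rnorm(1, 0.03, 0.07))
  national <- data.frame(year = yrs, rice_price_mean = price,
                         rice_price_sd = 0.08 * price * (1 + 0.5 * abs(rnorm(ny))))

  list(years = yrs,
       popdens = popdens,
       drought_pdsi = climate(0, 1.5, 0.5, 0.3, clip = c(-6, 6)),
       max_precip = climate(110, 25, 15, 8, clip = c(0, Inf)),
       max_temp = climate(33, 1.2, 0.8, 0.4),
       max_wind = climate(16, 4, 3, 1.5, clip = c(0, Inf)),
       national = national)
}

#' Simulate absorbing forest-loss dynamics
#'
#' Each forested base cell is cleared in year *t* with probability
#' `plogis(intercept + cell effect + psi * X_it + shock_t)`; clearing is
#' absorbing (no regrowth), so cover is monotone non-increasing.
#'
#' The configured yearly CFM effect `delta_true` (and any differential
#' pre-trend) is defined on the cell-area probability scale at the analysis
#' resolution as a *causal contrast*: in an effect year the expected annual
#' deforestation of a treated analysis cell exceeds that of the same cell
#' under the never-treated counterfactual by exactly `delta`. Because loss
#' is absorbing, earlier treatment depletes the forest available later and
#' shifts edge distances, so a naive constant hazard boost would make
#' later-year effects smaller than configured. The simulator therefore
#' evolves the counterfactual forest alongside the actual one with common
#' random numbers and raises the per-subcell hazard of still-forested
#' treated cells by exactly the amount that makes the expected block-level
#' contrast equal `delta` each year.
#'
#' @param scenario A scenario (or its static parts): needs `init_forest`,
#'   `cell_effect`, `management`, `time_variant`.
#' @param config The [sim_config()].
#' @param seed RNG seed for the clearing draws.
#' @return A binary-base-resolution [forest_cover_series()].
#' @export
simulate_forest_dynamics <- function(scenario, config,
                                     seed = derive_seed(config$seed, "dynamics")) {
  stopifnot(inherits(config, "sim_config"))
  for (fld in c("init_forest", "cell_effect", "management", "time_variant"))
    if (is.null(scenario[[fld]]))
      stop_defoeval(sprintf("scenario is missing '%s'", fld),
                    "defoeval_argument_error")
  tv <- scenario$time_variant
  for (nm in setdiff(names(config$psi_true), "dist_forest_edge"))
    if (any(!is.finite(tv[[nm]])))
      stop_defoeval(sprintf("non-finite values in covariate '%s'", nm),
                    "defoeval_validation_error")

  nr <- config$grid_rows; nc <- config$grid_cols
  yrs <- config$cover_years; ny <- length(yrs)
  af <- config$analysis_factor
  nrb <- (nr %/% af) * af; ncb <- (nc %/% af) * af

  kind_by_unit <- stats::setNames(scenario$management$units$kind,
                                  scenario$management$units$unit_id)
  uid <- scenario$management$unit_id
  is_cfm <- matrix(FALSE, nr, nc)
  is_cfm[!is.na(uid)] <- kind_by_unit[as.character(uid[!is.na(uid)])] == "CFM"

  mod_field <- NULL
  if (!is.null(config$effect_moderator)) {
    m <- scenario$static[[config$effect_moderator]]
    if (is.null(m))
      stop_defoeval(sprintf("unknown effect_moderator '%s'", config$effect_moderator),
                    "defoeval_argument_error")
    mod_field <- zscore(m)
  }

  sched <- true_effect_schedule(config)
  shocks <- stats::setNames(rep(0, ny), yrs)
  if (length(config$year_shocks))
    shocks[intersect(names(config$year_shocks), names(shocks))] <-
      config$year_shocks[intersect(names(config$year_shocks), names(shocks))]

  # block-level sums expanded back to base resolution
  expand_blocks <- function(bm) {
    out <- matrix(0, nr, nc)
    out[seq_len(nrb), seq_len(ncb)] <-
      bm[rep(seq_len(nrow(bm)), each = af), rep(seq_len(ncol(bm)), each = af)]
    out
  }
  block_sum <- function(m) block_mean(m[seq_len(nrb), seq_len(ncb)], af) * af^2

  with_seed(seed, {
    forest <- scenario$init_forest   # realized (treated) landscape
    forest_cf <- forest              # never-treated counterfactual
    cover <- array(0, c(nr, nc, ny))
    cover[, , 1] <- forest * 100
    any_effect <- length(config$delta_true) > 0 || config$pretrend_cfm != 0

    for (k in 2:ny) {
      yr <- as.character(yrs[k])
      eta <- config$hazard_intercept + scenario$cell_effect + shocks[[yr]]
      for (nm in setdiff(names(config$psi_true), "dist_forest_edge"))
        eta <- eta + config$psi_true[[nm]] * tv[[nm]][, , k]
      psi_edge <- config$psi_true[["dist_forest_edge"]] %||% 0
      if (is.na(psi_edge)) psi_edge <- 0
      p_act <- plogis(eta + psi_edge * edge_distance_matrix(forest, 30) / 1000)
      p_cf <- if (any_effect) {
        plogis(eta + psi_edge * edge_distance_matrix(forest_cf, 30) / 1000)
      } else p_act

      extra <- sched[[yr]] +
        config$pretrend_cfm / 100 * (yrs[k] - config$cover_years[1])
      delta_cell <- if (is.null(mod_field)) extra else extra * (1 + mod_field)
      p <- p_act
      # compensation stays active from the first effect year on: once the
      # treated and counterfactual histories diverge, holding the yearly
      # contrast at its configured value (including 0) requires offsetting
      # the depletion and edge-shift echoes of past treatment
      if (any_effect) {
        # hazard boost that makes the expected treated-vs-counterfactual
        # contrast equal delta per analysis block:
        #   sum_act (p + boost) - sum_cf p_cf = delta * block_area
        n_act <- block_sum(forest * 1)
        gap <- block_sum(p_cf * forest_cf) - block_sum(p_act * forest)
        dblk <- block_sum((if (length(delta_cell) == 1)
          matrix(delta_cell, nr, nc) else delta_cell) * is_cfm) /
          pmax(block_sum(is_cfm * 1), 1)
        boost_blk <- ifelse(n_act > 0, (dblk * af^2 + gap) / pmax(n_act, 1), 0)
        padd <- expand_blocks(boost_blk) * is_cfm
        p <- pmin(1, pmax(0, p_act + padd))
      }

      u <- matrix(runif(nr * nc), nr, nc)
      forest_new <- forest & !(u < p)
      if (any_effect) forest_cf <- forest_cf & !(u < p_cf)
      forest <- forest_new
      if (!any_effect) forest_cf <- forest
      cover[, , k] <- forest * 100
    }
    forest_cover_series(cover, yrs, 30, check = FALSE)
  })
}

# Distance (meters) from each forested cell to the nearest non-forest cell;
# internal fast path used inside the dynamics loop.
edge_distance_matrix <- function(forest, resolution) {
  if (!any(!forest)) {
    return(matrix(sqrt(sum((dim(forest) * resolution)^2)),
                  nrow(forest), ncol(forest)))
  }
  if (!any(forest)) return(matrix(0, nrow(forest), ncol(forest)))
  dm <- EBImage::distmap(matrix(as.numeric(forest), nrow(forest), ncol(forest)))
  as.matrix(dm) * resolution
}
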