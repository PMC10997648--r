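# Outcome construction: annual deforestation from gridded forest cover,
# multi-resolution aggregation, and the annually updated distance to the
# forest edge.

#' Construct a forest-cover series
#'
#' A forest-cover series holds, for every grid cell and year, the percentage
#' of the cell covered by forest. At the 30 m base resolution cover is binary
#' (0 or 100); aggregation to 90/270 m yields quasi-continuous percentages.
#' Cover must be non-increasing over time: forest loss is absorbing and
#' regrowth is not represented, as there is little evidence of natural forest
#' regeneration after clearing in the study system.
#'
#' @param cover Numeric 3-d array `[row, col, year]` with values in
#'   `[0, 100]`.
#' @param years Integer vector of contiguous calendar years, one per slice.
#' @param resolution Cell size in meters (30, 90 or 270 in the standard
#'   analyses).
#' @param origin Planar coordinates of the grid's lower-left corner.
#' @param check If `TRUE`, validate range, monotonicity, and year contiguity.
#' @return An object of class `forest_cover_series`.
#' @export
forest_cover_series <- function(cover, years, resolution,
                                origin = c(0, 0), check = TRUE) {
  stopifnot(is.array(cover), length(dim(cover)) == 3,
            dim(cover)[3] == length(years))
  years <- as.integer(years)
  if (check) {
    if (any(!is.finite(cover)) || min(cover) < 0 || max(cover) > 100)
      stop_defoeval("cover values must be finite and within [0, 100]",
                    "defoeval_range_error")
    if (length(years) > 1) {
      if (any(diff(years) != 1L))
        stop_defoeval("cover years must be contiguous", "defoeval_years_error")
      if (any(cover[, , -1] - cover[, , -length(years)] > 1e-9))
        stop_defoeval("cover must be non-increasing over years (no regrowth)",
                      "defoeval_monotonicity_error")
    }
  }
  dimnames(cover) <- list(NULL, NULL, years)
  structure(list(cover = cover, years = years,
                 resolution = as.numeric(resolution),
                 origin = as.numeric(origin)),
            class = "forest_cover_series")
}

#' @export
print.forest_cover_series <- function(x, ...) {
  d <- dim(x$cover)
  cat(sprintf("<forest_cover_series> %d x %d cells at %g m, years %d-%d\n",
              d[1], d[2], x$resolution, min(x$years), max(x$years)))
  cat(sprintf("  mean cover %d: %.1f%%; mean cover %d: %.1f%%\n",
              min(x$years), mean(x$cover[, , 1]),
              max(x$years), mean(x$cover[, , d[3]])))
  invisible(x)
}

#' Annual deforestation from a forest-cover series
#'
#' Deforestation in year *t* is the year-on-year drop in cover,
#' `cover[t-1] - cover[t]`, in percentage points of cell area; positive
#' values indicate forest loss. The first cover year has no predecessor and
#' is dropped. Annual (rather than cumulative) loss is used because it is
#' stationary, which the downstream panel regression assumes.
#'
#' @param cover A [forest_cover_series()] with at least two years.
#' @param mode `"strict"` errors if any cell regrows (cover increases);
#'   `"lenient"` clips negative losses to 0 with a warning.
#' @return An object of class `deforestation_series` with fields `value`
#'   (array `[row, col, year]`), `years`, `resolution`, `origin`.
#' @export
annual_deforestation <- function(cover, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cover, "forest_cover_series"))
  ny <- length(cover$years)
  if (ny < 2)
    stop_defoeval("need at least two cover years to difference",
                  "defoeval_insufficient_series")
  val <- cover$cover[, , -ny, drop = FALSE] - cover$cover[, , -1, drop = FALSE]
  if (any(val < -1e-9)) {
    if (mode == "strict")
      stop_defoeval("regrowth present: cover increases between years",
                    "defoeval_monotonicity_error")
    warning("regrowth present; negative deforestation clipped to 0")
    val[val < 0] <- 0
  }
  val[val < 0] <- 0  # scrub floating-point dust
  years <- cover$years[-1]
  dimnames(val) <- list(NULL, NULL, years)
  structure(list(value = val, years = years, resolution = cover$resolution,
                 origin = cover$origin),
            class = "deforestation_series")
}

#' Aggregate forest cover to a coarser resolution
#'
#' Each coarse cell's cover is the arithmetic mean of its `factor` x `factor`
#' block of fine cells, so total forest area is conserved exactly across
#' resolutions. The standard analyses aggregate 30 m binary cover to 90 and
#' 270 m (factors 3 and 9), which also turns the binary outcome into a
#' quasi-continuous percentage. Trailing rows/columns that do not fill a
#' complete block are dropped with a warning, keeping block means exact.
#'
#' @param cover A [forest_cover_series()].
#' @param factor Positive integer aggregation factor (3 or 9 in the standard
#'   analyses).
#' @return A [forest_cover_series()] at `resolution * factor` meters.
#' @export
aggregate_cover <- function(cover, factor) {
  stopifnot(inherits(cover, "forest_cover_series"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor))
    stop_defoeval("aggregation factor must be a positive integer",
                  "defoeval_argument_error")
  factor <- as.integer(factor)
  if (factor == 1L) return(cover)
  d <- dim(cover$cover)
  nr <- (d[1] %/% factor) * factor
  nc <- (d[2] %/% factor) * factor
  if (nr < factor || nc < factor)
    stop_defoeval("grid smaller than one aggregation block",
                  "defoeval_argument_error")
  if (nr < d[1] || nc < d[2])
    warning(sprintf("dropping %d trailing row(s) and %d column(s) not filling a %dx%d block",
                    d[1] - nr, d[2] - nc, factor, factor))
  out <- vapply(seq_len(d[3]), function(k) {
    block_mean(cover$cover[seq_len(nr), seq_len(nc), k], factor)
  }, matrix(0.0, nr %/% factor, nc %/% factor))
  out <- array(out, c(nr %/% factor, nc %/% factor, d[3]))
  forest_cover_series(out, cover$years, cover$resolution * factor,
                      origin = cover$origin, check = FALSE)
}

# Mean over factor x factor blocks of a matrix whose dims are multiples of
# `factor`.
block_mean <- function(m, factor) {
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  # sum within row-blocks, then within col-blocks
  g1 <- rowsum(m, rep(seq_len(nr), each = factor))
  g2 <- rowsum(t(g1), rep(seq_len(nc), each = factor))
  t(g2) / factor^2
}

#' Euclidean distance to the forest edge
#'
#' For each forested cell (cover > 0, the same threshold used for sampling
#' eligibility), the center-to-center Euclidean distance in meters to the
#' nearest non-forest cell in the given year. Non-forest cells get 0. A grid
#' with no non-forest cell gets the sentinel value equal to the grid
#' diagonal. Distances are planar; the synthetic grids carry no projection.
#'
#' @param cover A [forest_cover_series()].
#' @param year Calendar year present in the series.
#' @return Numeric matrix of distances in meters.
#' @export
distance_to_forest_edge <- function(cover, year) {
  stopifnot(inherits(cover, "forest_cover_series"))
  k <- match(as.integer(year), cover$years)
  if (is.na(k))
    stop_defoeval(sprintf("year %s not in cover series", year),
                  "defoeval_lookup_error")
  forest <- cover$cover[, , k] > 0
  d <- dim(forest)
  if (all(forest)) {
    diag_len <- sqrt(sum((d * cover$resolution)^2))
    return(matrix(diag_len, d[1], d[2]))
  }
  if (!any(forest)) return(matrix(0, d[1], d[2]))
  # distmap: exact Euclidean distance (in cell units) to the nearest
  # zero-valued (non-forest) cell; 0 on non-forest cells themselves.
  dm <- EBImage::distmap(matrix(as.numeric(forest), d[1], d[2]))
  as.matrix(dm) * cover$resolution
}

#' Total forest area in hectares
#'
#' @param cover A [forest_cover_series()].
#' @param year Calendar year; defaults to the first year.
#' @return Area in hectares.
#' @export
forest_area_ha <- function(cover, year = cover$years[1]) {
  k <- match(as.integer(year), cover$years)
  if (is.na(k))
    stop_defoeval(sprintf("year %s not in cover series", year),
                  "defoeval_lookup_error")
  cell_ha <- (cover$resolution^2) / 1e4
  sum(cover$cover[, , k] / 100) * cell_ha
}

#' Percentage decline in forest area between two dates
#'
#' The headline bookkeeping statistic: `100 * (start - end) / start`,
#' expressed as a percentage of the starting area.
#'
#' @param start_area,end_area Forest areas (same units) at the start and end
#'   of the window.
#' @return Decline in percent.
#' @export
forest_decline_pct <- function(start_area, end_area) {
  stopifnot(is.numeric(start_area), is.numeric(end_area))
  if (any(start_area <= 0))
    stop_defoeval("starting area must be positive", "defoeval_argument_error")
  100 * (start_area - end_area) / start_area
}
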