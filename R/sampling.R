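# Management-unit map and spatially balanced sampling of forested grid
# cells within CFM and MNP units.

#' Construct a management map
#'
#' Per-cell management-unit membership plus a unit attribute table. Cells
#' with overlapping CFM/MNP designations (claimed by both kinds) carry
#' `overlap = TRUE` and belong to no unit; such cells are excluded from all
#' sampling and comparison sets.
#'
#' @param unit_id Integer matrix of unit ids (`NA` = unmanaged).
#' @param units Data frame with columns `unit_id`, `kind` (`"CFM"`, `"MNP"`
#'   or `"OTHER"`), `established_year`, `renewed`, `vegetation_zone`
#'   (1 = eastern humid, 2 = western deciduous, 3 = southern spiny),
#'   `region_id`.
#' @param overlap Logical matrix flagging overlapping designations.
#' @param vegetation_zone Optional integer matrix of per-cell zones.
#' @param region Optional integer matrix of per-cell regions.
#' @return A `management_map` object.
#' @export
management_map <- function(unit_id, units, overlap = NULL,
                           vegetation_zone = NULL, region = NULL) {
  stopifnot(is.matrix(unit_id), is.data.frame(units))
  need <- c("unit_id", "kind", "established_year", "renewed",
            "vegetation_zone", "region_id")
  miss <- setdiff(need, names(units))
  if (length(miss))
    stop_defoeval(paste("units table missing columns:",
                        paste(miss, collapse = ", ")),
                  "defoeval_argument_error")
  if (!all(units$kind %in% c("CFM", "MNP", "OTHER")))
    stop_defoeval("unit kind must be CFM, MNP or OTHER",
                  "defoeval_argument_error")
  if (anyDuplicated(units$unit_id))
    stop_defoeval("duplicate unit ids", "defoeval_argument_error")
  if (is.null(overlap)) overlap <- matrix(FALSE, nrow(unit_id), ncol(unit_id))
  structure(list(unit_id = unit_id, units = units, overlap = overlap,
                 vegetation_zone = vegetation_zone, region = region),
            class = "management_map")
}

# Aggregate a base-resolution management map to the analysis resolution:
# a coarse cell inherits the modal unit of its block (ties to the lowest
# unit id); it is overlap-flagged if its block contains cells claimed by
# both kinds (directly or via the overlap mask).
aggregate_management <- function(management, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(management)
  uid <- management$unit_id
  nr <- (nrow(uid) %/% factor) * factor
  nc <- (ncol(uid) %/% factor) * factor
  crow <- nr %/% factor; ccol <- nc %/% factor
  kind_by_unit <- stats::setNames(management$units$kind,
                                  management$units$unit_id)
  bi <- rep(seq_len(crow), each = factor)
  bj <- rep(seq_len(ccol), each = factor)
  blk <- matrix(bi, nr, nc) + (matrix(bj, nr, nc, byrow = TRUE) - 1L) * crow
  dt <- data.table::data.table(blk = as.vector(blk),
                               uid = as.vector(uid[seq_len(nr), seq_len(nc)]),
                               ov = as.vector(management$overlap[seq_len(nr),
                                                                 seq_len(nc)]))
  out_ov <- matrix(FALSE, crow, ccol)
  ovb <- dt[, list(ov = any(ov)), by = "blk"]
  out_ov[ovb$blk] <- ovb$ov
  du <- dt[!is.na(dt$uid), ]
  out_id <- matrix(NA_integer_, crow, ccol)
  if (nrow(du)) {
    du$kind <- kind_by_unit[as.character(du$uid)]
    kmix <- du[du$kind != "OTHER",
               list(mix = length(unique(kind)) > 1), by = "blk"]
    out_ov[kmix$blk[kmix$mix]] <- TRUE
    cnt <- du[, list(n = .N), by = c("blk", "uid")]
    cnt <- cnt[order(cnt$blk, -cnt$n, cnt$uid), ]
    top <- cnt[!duplicated(cnt$blk), ]
    out_id[top$blk] <- top$uid
  }
  shrink <- function(m) if (is.null(m)) NULL else
    m[seq(1 + factor %/% 2, nr, by = factor),
      seq(1 + factor %/% 2, nc, by = factor), drop = FALSE]
  management_map(out_id, management$units, out_ov,
                 vegetation_zone = shrink(management$vegetation_zone),
                 region = shrink(management$region))
}

#' Cells eligible for sampling
#'
#' Applies the sampling rules: cells inside units of the requested kinds
#' established before the baseline cutoff, with more than 0% forest cover at
#' baseline, and not in areas claimed by both a CFM and an MNP designation
#' (overlap exclusion). `renewed_only` restricts CFM cells to units whose
#' contract was renewed.
#'
#' @param management A [management_map()] at the analysis resolution.
#' @param cover A [forest_cover_series()] at the same resolution.
#' @param baseline_year Baseline year (default 2005).
#' @param kinds Unit kinds to include.
#' @param renewed_only Restrict CFM to renewed contracts.
#' @return Data frame of eligible cells: `cell_id`, `row`, `col`, `x`, `y`,
#'   `unit_id`, `kind`, `treatment` (1 = CFM, 0 = MNP), `vegetation_zone`,
#'   `region_id`, with attribute `empty = TRUE` when no cell qualifies.
#' @export
eligible_cells <- function(management, cover, baseline_year = 2005,
                           kinds = c("CFM", "MNP"), renewed_only = FALSE) {
  stopifnot(inherits(management, "management_map"),
            inherits(cover, "forest_cover_series"))
  k <- match(as.integer(baseline_year), cover$years)
  if (is.na(k))
    stop_defoeval("baseline year not in cover series", "defoeval_lookup_error")
  uid <- management$unit_id
  stopifnot(all(dim(uid) == dim(cover$cover)[1:2]))
  units <- management$units
  keep_units <- units[units$kind %in% kinds &
                        units$established_year < baseline_year, ]
  if (renewed_only)
    keep_units <- keep_units[keep_units$kind != "CFM" | keep_units$renewed, ]
  ok_unit <- uid %in% keep_units$unit_id & !management$overlap &
    cover$cover[, , k] > 0
  idx <- which(matrix(ok_unit, nrow(uid), ncol(uid)), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- data.frame(cell_id = integer(), row = integer(), col = integer(),
                      x = numeric(), y = numeric(), unit_id = integer(),
                      kind = character(), treatment = integer(),
                      vegetation_zone = integer(), region_id = integer())
    attr(out, "empty") <- TRUE
    return(out)
  }
  uvec <- uid[idx]
  urow <- keep_units[match(uvec, keep_units$unit_id), ]
  res <- cover$resolution
  out <- data.frame(cell_id = (idx[, 1] - 1L) * ncol(uid) + idx[, 2],
                    row = idx[, 1], col = idx[, 2],
                    x = cover$origin[1] + (idx[, 2] - 0.5) * res,
                    y = cover$origin[2] + (idx[, 1] - 0.5) * res,
                    unit_id = uvec, kind = urow$kind,
                    treatment = as.integer(urow$kind == "CFM"),
                    vegetation_zone = urow$vegetation_zone,
                    region_id = urow$region_id)
  if (!is.null(management$vegetation_zone))
    out$vegetation_zone <- management$vegetation_zone[idx]
  out <- out[order(out$cell_id), ]
  rownames(out) <- NULL
  attr(out, "empty") <- FALSE
  out
}

#' Spatially balanced sample of cells
#'
#' Recursive quadrant-stratified draw: the bounding box of the candidate
#' cells is split into four quadrants, the sample size is allocated to
#' quadrants proportionally to their eligible-cell counts (largest-remainder
#' rounding), and the procedure recurses until an allocation falls below the
#' leaf size, where cells are drawn uniformly without replacement. The
#' resulting sample represents each part of the study area roughly in
#' proportion to its share of eligible cells — the stated property of the
#' spatially balanced point tool the original analysis used — and is fully
#' deterministic given the seed.
#'
#' @param cells Data frame from [eligible_cells()] (needs `row`, `col`).
#' @param n Number of cells to draw (`n <= nrow(cells)`).
#' @param seed Integer seed.
#' @param leaf_size Allocations at or below this size are drawn uniformly.
#' @return `cells[drawn, ]`, ordered by `cell_id`, with attributes `seed`
#'   and `n`.
#' @export
spatially_balanced_sample <- function(cells, n, seed, leaf_size = 8L) {
  stopifnot(is.data.frame(cells))
  if (n > nrow(cells))
    stop_defoeval(sprintf("requested %d cells from a pool of %d", n, nrow(cells)),
                  "defoeval_sampling_error")
  if (n == nrow(cells)) {
    out <- cells[order(cells$cell_id), ]
    rownames(out) <- NULL
    attr(out, "seed") <- seed; attr(out, "n") <- n
    return(out)
  }
  draw <- with_seed(seed, quad_sample(cells, n, leaf_size))
  out <- cells[sort(draw), ]
  out <- out[order(out$cell_id), ]
  rownames(out) <- NULL
  attr(out, "seed") <- seed; attr(out, "n") <- n
  out
}

# Largest-remainder (Hamilton) apportionment of n among counts.
largest_remainder <- function(n, counts) {
  if (sum(counts) == 0) return(rep(0L, length(counts)))
  q <- n * counts / sum(counts)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  # never allocate more than available
  over <- base > counts
  while (any(over)) {
    excess <- sum(base[over] - counts[over])
    base[over] <- counts[over]
    room <- which(base < counts)
    ord <- room[order(counts[room] - base[room], decreasing = TRUE)]
    i <- 1
    while (excess > 0 && length(ord)) {
      base[ord[i]] <- base[ord[i]] + 1
      excess <- excess - 1
      i <- if (i == length(ord)) 1 else i + 1
    }
    over <- base > counts
  }
  as.integer(base)
}

quad_sample <- function(cells, n, leaf_size, idx = seq_len(nrow(cells))) {
  if (n == 0) return(integer())
  if (n >= length(idx)) return(idx)
  if (n <= leaf_size || length(idx) <= 2 * leaf_size)
    return(idx[sample.int(length(idx), n)])
  r <- cells$row[idx]; cl <- cells$col[idx]
  rmid <- (min(r) + max(r)) / 2; cmid <- (min(cl) + max(cl)) / 2
  quads <- list(idx[r <= rmid & cl <= cmid], idx[r <= rmid & cl > cmid],
                idx[r > rmid & cl <= cmid], idx[r > rmid & cl > cmid])
  counts <- lengths(quads)
  if (sum(counts > 0) < 2)  # degenerate split: fall back to uniform
    return(idx[sample.int(length(idx), n)])
  alloc <- largest_remainder(n, counts)
  unlist(lapply(seq_len(4), function(q)
    quad_sample(cells, alloc[q], leaf_size, quads[[q]])), use.names = FALSE)
}
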