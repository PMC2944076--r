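# Regional aggregation, table formatting, percent-change and density-map
# reporting conventions. Table entries are reported in thousands of
# deaths/YLL as "mean +- 1 SD"; percent changes are computed from unrounded
# totals and rounded half-away-from-zero to one decimal; World rows are
# summed before rounding.

#' Round half away from zero
#'
#' Ties go away from zero (`0.5 -> 1`, `-0.5 -> -1`), unlike base `round()`'s
#' round-half-even; this is the convention of the printed tables.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Aggregate a burden surface over regions
#'
#' Sums excess mortality and YLL over the cells of each region and appends a
#' World row equal to the sum of the region rows (summation before any
#' rounding). Burden in a cell without a region assignment is a coverage
#' error.
#'
#' @param burden A [burden_surface()].
#' @param regions A [region_map()] on the same grid.
#' @return Data frame with columns `region`, `mort`, `yll` (unrounded,
#'   deaths/year and years/year), one row per region plus `"World"`.
#' @export
aggregate_regions <- function(burden, regions) {
  stopifnot(inherits(burden, "burden_surface"),
            inherits(regions, "region_map"))
  stop_if_grid_mismatch(burden$mort$grid, regions$grid)
  none <- is.na(regions$region)
  if (any(burden$mort$values[none] > 0))
    stop("coverage error: burden in cell(s) without a region", call. = FALSE)
  rnames <- region_names()
  codes <- match(regions$region, rnames)
  codes[is.na(codes)] <- 0L
  mort <- region_sums(as.vector(burden$mort$values), as.vector(codes),
                      length(rnames))
  yll <- region_sums(as.vector(burden$yll$values), as.vector(codes),
                     length(rnames))
  data.frame(region = c(rnames, "World"), mort = mort, yll = yll)
}

#' Percent change between two totals
#'
#' `100 * (alternative - baseline) / baseline`, rounded half-away-from-zero
#' to one decimal. Computed from unrounded totals; the baseline must be
#' positive.
#'
#' @param alternative,baseline Totals (same units).
#' @return Signed percentage at 0.1 resolution.
#' @examples
#' percent_change(470, 700)   # -32.9
#' percent_change(2506, 3499) # -28.4
#' @export
percent_change <- function(alternative, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("undefined percent change: baseline must be > 0", call. = FALSE)
  round_half_away(100 * (alternative - baseline) / baseline, 1)
}

#' Burden density maps
#'
#' Per-area burden (`dMort / (area / 1000)`, deaths per 1,000 km^2) and
#' per-capita burden (`dMort / (pop / 1e6)`, deaths per million people,
#' reported as missing — not zero — where the population is zero).
#'
#' @param burden A [burden_surface()].
#' @param areas Cell-area `gridded_field` (km^2), e.g. [cell_areas()].
#' @param pop Population `gridded_field`.
#' @return List of `gridded_field`s `per_area`, `per_capita`.
#' @export
density_maps <- function(burden, areas, pop) {
  stopifnot(inherits(burden, "burden_surface"))
  stop_if_grid_mismatch(burden$mort$grid, areas$grid)
  stop_if_grid_mismatch(burden$mort$grid, pop$grid)
  g <- burden$mort$grid
  per_area <- burden$mort$values / (areas$values / 1000)
  pc <- burden$mort$values / (pop$values / 1e6)
  pc[pop$values == 0] <- NA_real_
  list(per_area = gridded_field(g, per_area, "deaths/1000km2"),
       per_capita = gridded_field(g, pc, "deaths/1e6 people"))
}

# "mean +- sd" in thousands, integer-rounded half away from zero
format_entry <- function(mean, sd) {
  sprintf("%d ± %d", as.integer(round_half_away(mean / 1000)),
          as.integer(round_half_away(sd / 1000)))
}

#' Format Monte Carlo burden tables
#'
#' Renders the regional mortality and YLL tables in the reporting
#' convention: entries in thousands, integer-rounded half-away-from-zero,
#' as `"mean +- sd"`; World rows summed before rounding. A provenance block
#' (CRF models, thresholds, draw count, seed) is attached and written
#' alongside the CSVs when `out` is given.
#'
#' @param mc An [mc_burden()] result.
#' @param out Optional output directory; writes `regional_mortality.csv`,
#'   `regional_yll.csv` and `provenance.txt`.
#' @return List with `mortality` and `yll` data frames of formatted entries
#'   (rows = regions + World, one column per pollutant-cause pair) and
#'   `provenance` (character vector).
#' @export
format_tables <- function(mc, out = NULL) {
  stopifnot(inherits(mc, "mc_result"))
  rows <- c(region_names(), "World")
  fmt_one <- function(col_mean, col_sd) {
    vapply(seq_along(col_mean), function(i) format_entry(col_mean[i],
                                                         col_sd[i]), "")
  }
  mortality <- data.frame(region = rows)
  yll <- data.frame(region = rows)
  for (pn in names(mc$pairs)) {
    reg <- mc$pairs[[pn]]$regional
    mortality[[pn]] <- fmt_one(reg$mort_mean, reg$mort_sd)
    yll[[pn]] <- fmt_one(reg$yll_mean, reg$yll_sd)
  }
  prov <- c(
    "airburden run provenance",
    sprintf("draws: %d, seed: %s, conc_sd: %.3f (%s), truncate_negative: %s",
            mc$config$n_draws, format(mc$config$seed),
            mc$config$conc_sd_fraction, mc$config$conc_mode,
            mc$config$truncate_negative),
    vapply(mc$point$provenance$crfs, function(x)
      sprintf("crf: %s/%s model=%s beta=%.6g se=%.6g",
              x$pollutant, x$cause, x$model, x$beta, x$beta_se), ""),
    vapply(names(mc$point$provenance$policy), function(p) {
      pol <- mc$point$provenance$policy[[p]]
      sprintf("policy %s: lct=%s hct=%s", p,
              if (is.null(pol$lct)) "none" else format(pol$lct),
              if (is.null(pol$hct)) "none" else format(pol$hct))
    }, "")
  )
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(mortality, file.path(out, "regional_mortality.csv"),
                     row.names = FALSE)
    utils::write.csv(yll, file.path(out, "regional_yll.csv"),
                     row.names = FALSE)
    writeLines(prov, file.path(out, "provenance.txt"))
  }
  list(mortality = mortality, yll = yll, provenance = prov)
}
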