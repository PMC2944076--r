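# Country/region vital statistics and their projection onto the grid.
#
# Baseline mortality rates are country-specific where available and fall back
# to the country's regional rate otherwise. Rates, the adult population
# fraction, and baseline years of life lost per death (YLL0) are gridded via
# cell-to-country area weights; cells overlapping several countries receive
# the area-weighted average.

CAUSES <- c("respiratory", "cardiopulmonary", "lung_cancer", "all_cause")

#' Country and region vital-statistics tables
#'
#' @param countries Data frame with columns `country_code`, `region_id`,
#'   `cause`, `rate` (fraction/year, in `[0, 0.1]`), `available` (logical;
#'   `FALSE` means the country-specific rate is missing and the regional
#'   fallback applies).
#' @param regions Data frame with columns `region_id`, `cause`, `rate`
#'   (regional fallback rate, fraction/year), `fraction_30plus` (share of the
#'   population aged >= 30, constant within a region), `yll0` (baseline years
#'   of life lost per death, years, in `(0, 40)`).
#' @return Object of class `demography_tables`.
#' @export
demography_tables <- function(countries, regions) {
  stopifnot(is.data.frame(countries), is.data.frame(regions))
  need_c <- c("country_code", "region_id", "cause", "rate", "available")
  need_r <- c("region_id", "cause", "rate", "fraction_30plus", "yll0")
  stopifnot(all(need_c %in% names(countries)), all(need_r %in% names(regions)))
  stopifnot(all(countries$cause %in% CAUSES), all(regions$cause %in% CAUSES))
  ok_rate <- function(r) all(is.finite(r) & r >= 0 & r <= 0.1)
  if (!ok_rate(countries$rate[countries$available]) || !ok_rate(regions$rate))
    stop("mortality rates must lie in [0, 0.1] per year", call. = FALSE)
  stopifnot(all(regions$fraction_30plus >= 0 & regions$fraction_30plus <= 1),
            all(regions$yll0 > 0 & regions$yll0 < 40))
  # fraction_30plus must not vary across cause rows of one region
  fr <- tapply(regions$fraction_30plus, regions$region_id,
               function(v) diff(range(v)))
  if (any(fr > 1e-12))
    stop("fraction_30plus must be constant within a region", call. = FALSE)
  if (!all(countries$region_id %in% regions$region_id))
    stop("every country must belong to a region present in the region table",
         call. = FALSE)
  structure(list(countries = countries, regions = regions),
            class = "demography_tables")
}

#' @export
print.demography_tables <- function(x, ...) {
  cat(sprintf("demography_tables: %d countries, %d regions, causes: %s\n",
              length(unique(x$countries$country_code)),
              length(unique(x$regions$region_id)),
              paste(unique(x$regions$cause), collapse = ", ")))
  invisible(x)
}

#' Cell-to-country area weights
#'
#' For each land cell, the fraction of its area falling in each country.
#' Weights are non-negative and sum to 1 within each cell (checked at use
#' with tolerance 1e-6). Ocean cells are simply absent from the table.
#'
#' @param weights Data frame with columns `cell_index` (zero-based row-major
#'   index, see [cell_index()]), `country_code`, `weight`.
#' @return Object of class `country_weight_map`.
#' @export
country_weight_map <- function(weights) {
  stopifnot(is.data.frame(weights),
            all(c("cell_index", "country_code", "weight") %in% names(weights)))
  if (any(weights$weight < 0))
    stop("weights must be >= 0", call. = FALSE)
  structure(list(weights = weights), class = "country_weight_map")
}

check_weight_sums <- function(wmap, tol = 1e-6) {
  s <- tapply(wmap$weights$weight, wmap$weights$cell_index, sum)
  bad <- abs(s - 1) > tol
  if (any(bad))
    stop(sprintf("weight error: %d cell(s) have weights not summing to 1 (first: cell %s, sum %.8f)",
                 sum(bad), names(s)[bad][1], s[bad][1]), call. = FALSE)
  invisible(TRUE)
}

#' Baseline mortality rate for one country and cause
#'
#' Returns the country-specific rate when available, otherwise the country's
#' regional rate (regional-rate substitution for countries whose
#' vital-statistics registration does not report the cause).
#'
#' @param country Country code.
#' @param cause One of `"respiratory"`, `"cardiopulmonary"`,
#'   `"lung_cancer"`, `"all_cause"`.
#' @param tables A [demography_tables()].
#' @return Rate in fraction/year.
#' @export
resolve_rate <- function(country, cause, tables) {
  stopifnot(inherits(tables, "demography_tables"))
  cc <- tables$countries
  row <- cc[cc$country_code == country & cc$cause == cause, , drop = FALSE]
  if (nrow(row) == 0)
    stop("lookup error: unknown country/cause: ", country, "/", cause,
         call. = FALSE)
  if (row$available[1]) return(row$rate[1])
  rr <- tables$regions
  fb <- rr[rr$region_id == row$region_id[1] & rr$cause == cause, , drop = FALSE]
  if (nrow(fb) == 0)
    stop("lookup error: no regional fallback rate for region ",
         row$region_id[1], ", cause ", cause, call. = FALSE)
  fb$rate[1]
}

#' Grid a baseline mortality rate
#'
#' Per cell, the area-weighted average of the contributing countries'
#' resolved rates (`sum_c w_c * rate_c`); ocean cells (absent from the weight
#' map) are 0 so burden sums need no masking.
#'
#' @param tables A [demography_tables()].
#' @param wmap A [country_weight_map()].
#' @param cause Cause of death.
#' @param grid The shared `grid_spec`.
#' @return A `gridded_field` of rates (fraction/year).
#' @export
rate_surface <- function(tables, wmap, cause, grid) {
  stopifnot(inherits(wmap, "country_weight_map"), is_grid_spec(grid))
  check_weight_sums(wmap)
  w <- wmap$weights
  codes <- unique(w$country_code)
  rates <- vapply(codes, resolve_rate, numeric(1),
                  cause = cause, tables = tables)
  contrib <- w$weight * rates[match(w$country_code, codes)]
  per_cell <- tapply(contrib, w$cell_index, sum)
  v <- matrix(0, grid$n_lat, grid$n_lon)
  idx <- cell_index_inv(grid, as.integer(names(per_cell)))
  v[cbind(idx$lat, idx$lon)] <- as.numeric(per_cell)
  gridded_field(grid, v, units = "1/year")
}

#' Population aged 30 and over
#'
#' Scales the total population surface by the regional adult fraction: per
#' cell, `pop * fraction_30plus(region)`. The concentration-response factors
#' apply to adults >= 30 (the cohort-study population), so burdens use this
#' surface.
#'
#' @param pop Total population `gridded_field`.
#' @param tables A [demography_tables()].
#' @param regions A [region_map()] on the same grid.
#' @return A `gridded_field` of adult population counts.
#' @export
adult_population <- function(pop, tables, regions) {
  stopifnot(is_gridded_field(pop), inherits(regions, "region_map"),
            inherits(tables, "demography_tables"))
  stop_if_grid_mismatch(pop$grid, regions$grid)
  rr <- tables$regions
  frac <- tapply(rr$fraction_30plus, rr$region_id, function(v) v[1])
  f <- matrix(0, pop$grid$n_lat, pop$grid$n_lon)
  has_region <- !is.na(regions$region)
  unknown <- setdiff(unique(regions$region[has_region]), names(frac))
  if (length(unknown))
    stop("coverage error: no fraction_30plus for region(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  f[has_region] <- frac[regions$region[has_region]]
  if (any(pop$values[!has_region] > 0, na.rm = TRUE))
    stop("coverage error: populated cell without a region", call. = FALSE)
  gridded_field(pop$grid, pop$values * f, units = pop$units)
}

#' Grid the baseline years of life lost per death
#'
#' YLL0 is tabulated per region and cause (3% discounting and non-uniform
#' age weights are already inside the tabulated values) and is constant
#' within a region; ocean cells are 0.
#'
#' @inheritParams adult_population
#' @param cause Cause of death.
#' @return A `gridded_field` (years/death).
#' @export
yll0_surface <- function(tables, regions, cause) {
  stopifnot(inherits(tables, "demography_tables"),
            inherits(regions, "region_map"))
  rr <- tables$regions[tables$regions$cause == cause, , drop = FALSE]
  if (nrow(rr) == 0)
    stop("no yll0 rows for cause ", cause, call. = FALSE)
  y <- stats::setNames(rr$yll0, rr$region_id)
  g <- regions$grid
  v <- matrix(0, g$n_lat, g$n_lon)
  has <- !is.na(regions$region)
  v[has] <- y[regions$region[has]]
  if (anyNA(v))
    stop("coverage error: region without yll0 for cause ", cause,
         call. = FALSE)
  gridded_field(g, v, units = "years/death")
}

# ---- CSV I/O ----------------------------------------------------------------

#' Read or write demography tables and cell weights as CSV
#'
#' Schemas: `countries.csv` (country_code, region_id, cause, rate,
#' available), `regions.csv` (region_id, cause, rate, fraction_30plus,
#' yll0), `weights.csv` (cell_index, country_code, weight).
#'
#' @param countries_path,regions_path,weights_path File paths.
#' @param tables A [demography_tables()] (for writing).
#' @param wmap A [country_weight_map()] (for writing).
#' @return Readers return the reconstructed object; writers return the
#'   path(s) invisibly.
#' @name demography_io
NULL

#' @rdname demography_io
#' @export
read_demography_tables <- function(countries_path, regions_path) {
  demography_tables(utils::read.csv(countries_path),
                    utils::read.csv(regions_path))
}

#' @rdname demography_io
#' @export
write_demography_tables <- function(tables, countries_path, regions_path) {
  utils::write.csv(tables$countries, countries_path, row.names = FALSE)
  utils::write.csv(tables$regions, regions_path, row.names = FALSE)
  invisible(c(countries_path, regions_path))
}

#' @rdname demography_io
#' @export
read_country_weights <- function(weights_path) {
  country_weight_map(utils::read.csv(weights_path))
}

#' @rdname demography_io
#' @export
write_country_weights <- function(wmap, weights_path) {
  utils::write.csv(wmap$weights, weights_path, row.names = FALSE)
  invisible(weights_path)
}
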