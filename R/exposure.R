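# Exposure metrics and anthropogenic concentration deltas.
#
# Chronic-exposure epidemiology uses two metrics: the 6-month seasonal mean of
# the daily 1-hr maximum for O3 (the high-ozone season differs by hemisphere,
# so the season is found per cell) and the annual mean mass for PM2.5
# (reconstructed from speciated aerosol components with full ammonium
# neutralisation of sulfate and nitrate).

#' Epidemiology-ready exposure surface
#'
#' @param metric `"o3_season_dmax1h"` or `"pm25_annual"`.
#' @param values `gridded_field` of concentrations (ppb or ug/m3).
#' @param window_start For the O3 metric, a `gridded_field` holding the first
#'   month (1-12) of each cell's highest 6-month window; `NULL` for PM2.5.
#' @return Object of class `exposure_surface`.
#' @export
exposure_surface <- function(metric = c("o3_season_dmax1h", "pm25_annual"),
                             values, window_start = NULL) {
  metric <- match.arg(metric)
  stopifnot(is_gridded_field(values))
  if (metric == "o3_season_dmax1h") {
    stopifnot(is_gridded_field(window_start))
    stop_if_grid_mismatch(values$grid, window_start$grid)
    ws <- window_start$values
    if (any(is.na(ws)) || any(ws < 1 | ws > 12 | ws != round(ws)))
      stop("window_start must hold integer months 1-12 for every cell",
           call. = FALSE)
  }
  structure(list(metric = metric, values = values,
                 window_start = window_start),
            class = "exposure_surface")
}

#' @export
print.exposure_surface <- function(x, ...) {
  cat("exposure_surface:", x$metric, "\n")
  print(x$values)
  invisible(x)
}

#' Seasonal O3 metric: best consecutive 6-month window
#'
#' For each grid cell, finds the consecutive 6-month period (wrapping across
#' the year boundary) with the highest mean of the monthly daily 1-hr maximum
#' O3, and returns that mean together with the window's first month. Ties are
#' broken toward the earliest start month.
#'
#' @param monthly A list of 12 `gridded_field`s (January..December monthly
#'   means of the daily 1-hr maximum, ppb), all on one grid and complete.
#' @return An `exposure_surface` with metric `"o3_season_dmax1h"`.
#' @export
o3_season_average <- function(monthly) {
  if (!is.list(monthly) || length(monthly) != 12 ||
      !all(vapply(monthly, is_gridded_field, TRUE)))
    stop("incomplete series: need a list of 12 monthly fields", call. = FALSE)
  g <- monthly[[1]]$grid
  for (m in monthly) stop_if_grid_mismatch(g, m$grid, "monthly fields")
  X <- vapply(monthly, function(f) as.vector(f$values), numeric(g$n_lat * g$n_lon))
  if (anyNA(X))
    stop("incomplete series: missing month value(s)", call. = FALSE)
  # W[m, w] = 1/6 if month m lies in the 6-month window starting at w (wrapped)
  W <- matrix(0, 12, 12)
  for (w in 1:12) W[(w + 0:5 - 1) %% 12 + 1, w] <- 1 / 6
  wm <- X %*% W                       # ncell x 12 window means
  best <- max.col(wm, ties.method = "first")
  seas <- wm[cbind(seq_len(nrow(wm)), best)]
  shape <- function(v) matrix(v, g$n_lat, g$n_lon)
  exposure_surface(
    "o3_season_dmax1h",
    gridded_field(g, shape(seas), units = monthly[[1]]$units),
    gridded_field(g, shape(best), units = "month")
  )
}

#' Aerosol speciation configuration
#'
#' Controls how speciated aerosol masses are combined into PM2.5. Organic
#' carbon mass is multiplied by 1.4 to account for non-carbon organic matter;
#' sulfate and nitrate are assumed fully neutralised as ammonium sulfate and
#' ammonium nitrate, via the molar-mass ratios 132.14/96.06 and 80.04/62.00.
#' In the default `drop_simulated_nh4` mode the simulated ammonium mass is
#' discarded (the salt factors already supply it); `add_simulated_nh4`
#' instead adds the simulated ammonium and uses unit salt factors, so
#' ammonium is never double counted.
#'
#' @param oc_multiplier Organic matter / organic carbon mass ratio (>= 1).
#' @param sulfate_salt_factor (NH4)2SO4 / SO4 molar mass ratio (>= 1).
#' @param nitrate_salt_factor NH4NO3 / NO3 molar mass ratio (>= 1).
#' @param ammonium_mode `"drop_simulated_nh4"` (default) or
#'   `"add_simulated_nh4"`.
#' @return Object of class `speciation_config`.
#' @export
speciation_config <- function(oc_multiplier = 1.4,
                              sulfate_salt_factor = 132.14 / 96.06,
                              nitrate_salt_factor = 80.04 / 62.00,
                              ammonium_mode = c("drop_simulated_nh4",
                                                "add_simulated_nh4")) {
  ammonium_mode <- match.arg(ammonium_mode)
  stopifnot(oc_multiplier >= 1, sulfate_salt_factor >= 1,
            nitrate_salt_factor >= 1)
  structure(list(oc_multiplier = oc_multiplier,
                 sulfate_salt_factor = sulfate_salt_factor,
                 nitrate_salt_factor = nitrate_salt_factor,
                 ammonium_mode = ammonium_mode),
            class = "speciation_config")
}

#' Reconstruct PM2.5 mass from aerosol species
#'
#' PM2.5 is defined as sulfate + nitrate + ammonium + black carbon + primary
#' organic matter; dust, sea salt and secondary organic aerosol never enter.
#' Under the default configuration
#' `PM2.5 = 1.375 SO4 + 1.291 NO3 + BC + 1.4 OC` (full ammonium
#' neutralisation, simulated NH4 dropped); in `add_simulated_nh4` mode
#' `PM2.5 = SO4 + NO3 + NH4 + BC + 1.4 OC`.
#'
#' @param species Named list of `gridded_field`s `so4`, `no3`, `nh4`, `bc`,
#'   `oc` (annual mean mass, ug/m3), all on one grid.
#' @param cfg A [speciation_config()].
#' @return An `exposure_surface` with metric `"pm25_annual"`.
#' @export
pm25_reconstruct <- function(species, cfg = speciation_config()) {
  need <- c("so4", "no3", "nh4", "bc", "oc")
  if (!all(need %in% names(species)))
    stop("species must contain: ", paste(need, collapse = ", "), call. = FALSE)
  g <- species$so4$grid
  for (nm in need) {
    f <- species[[nm]]
    stopifnot(is_gridded_field(f))
    stop_if_grid_mismatch(g, f$grid, "species surfaces")
    if (any(f$values[!is.na(f$values)] < 0))
      stop("negative species mass in ", nm, call. = FALSE)
  }
  v <- if (cfg$ammonium_mode == "drop_simulated_nh4") {
    cfg$sulfate_salt_factor * species$so4$values +
      cfg$nitrate_salt_factor * species$no3$values +
      species$bc$values + cfg$oc_multiplier * species$oc$values
  } else {
    species$so4$values + species$no3$values + species$nh4$values +
      species$bc$values + cfg$oc_multiplier * species$oc$values
  }
  exposure_surface("pm25_annual",
                   gridded_field(g, v, units = species$so4$units))
}

#' Low / high concentration threshold policy
#'
#' The LCT is the concentration below which no mortality effect is assumed
#' (it replaces the preindustrial baseline wherever it exceeds it); the HCT
#' caps the present-day concentration, reflecting ignorance of the
#' concentration-response relation beyond the highest measured level.
#'
#' @param lct Low concentration threshold in the metric's units, or `NULL`.
#' @param hct High concentration threshold, or `NULL`. If both are set,
#'   `lct < hct` is required.
#' @return Object of class `threshold_policy`.
#' @export
threshold_policy <- function(lct = NULL, hct = NULL) {
  if (!is.null(lct)) stopifnot(is.finite(lct), lct >= 0)
  if (!is.null(hct)) stopifnot(is.finite(hct), hct >= 0)
  if (!is.null(lct) && !is.null(hct) && lct >= hct)
    stop("threshold policy requires lct < hct", call. = FALSE)
  structure(list(lct = lct, hct = hct), class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("threshold_policy: lct=%s hct=%s\n",
              if (is.null(x$lct)) "none" else format(x$lct),
              if (is.null(x$hct)) "none" else format(x$hct)))
  invisible(x)
}

#' Anthropogenic exposure increase under a threshold policy
#'
#' Per cell, `dX = max(0, min(present, hct) - max(preindustrial, lct))`:
#' the counterfactual baseline is the larger of the preindustrial
#' concentration and the LCT, the effective present-day concentration is
#' capped at the HCT, and the difference is floored at zero (cells where the
#' baseline exceeds the effective present level contribute no burden).
#'
#' @param present,preindustrial `exposure_surface`s with matching metric and
#'   grid.
#' @param policy A [threshold_policy()]; the default applies no thresholds,
#'   so `dX` is the raw present-minus-preindustrial difference floored at 0.
#' @return Object of class `delta_exposure` with elements `values`
#'   (`gridded_field`, >= 0), `metric`, `policy`.
#' @export
delta_exposure <- function(present, preindustrial,
                           policy = threshold_policy()) {
  stopifnot(inherits(present, "exposure_surface"),
            inherits(preindustrial, "exposure_surface"),
            inherits(policy, "threshold_policy"))
  if (present$metric != preindustrial$metric)
    stop("metric mismatch: ", present$metric, " vs ", preindustrial$metric,
         call. = FALSE)
  stop_if_grid_mismatch(present$values$grid, preindustrial$values$grid,
                        "exposure surfaces")
  p <- present$values$values
  b <- preindustrial$values$values
  if (!is.null(policy$hct)) p <- pmin(p, policy$hct)
  if (!is.null(policy$lct)) b <- pmax(b, policy$lct)
  dx <- pmax(p - b, 0)  # matrix first: pmax keeps dims from its first argument
  structure(list(values = gridded_field(present$values$grid, dx,
                                        units = present$values$units),
                 metric = present$metric, policy = policy),
            class = "delta_exposure")
}

#' Population-weighted mean and range of a field
#'
#' `mean = sum(pop * x) / sum(pop)` over cells where both surfaces are
#' non-missing; `min`/`max` are the lowest and highest individual grid-cell
#' values over those cells (the "range" convention of regional exposure
#' summaries).
#'
#' @param field,pop `gridded_field`s on one grid; total population must be
#'   positive.
#' @return Named list `mean`, `min`, `max`.
#' @export
popweighted_stats <- function(field, pop) {
  stopifnot(is_gridded_field(field), is_gridded_field(pop))
  stop_if_grid_mismatch(field$grid, pop$grid)
  ok <- !is.na(field$values) & !is.na(pop$values)
  w <- pop$values[ok]
  x <- field$values[ok]
  if (sum(w) <= 0)
    stop("undefined mean: total population is zero", call. = FALSE)
  list(mean = sum(w * x) / sum(w), min = min(x), max = max(x))
}
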