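# Log-linear health impact functions.
#
# The chain per pollutant-cause pair is
#   RR = exp(beta * dX)
#   AF = (RR - 1) / RR = 1 - exp(-beta * dX)
#   dMort = y0 * AF * Pop
#   dYLL  = dMort * YLL0
# applied independently in every grid cell, where beta is the
# concentration-response factor (slope of the log-linear relation between
# concentration and mortality risk), dX the anthropogenic concentration
# increase, y0 the baseline mortality rate, Pop the exposed adult
# population, and YLL0 the baseline years of life lost per death.

POLLUTANT_METRIC <- c(o3 = "o3_season_dmax1h", pm25 = "pm25_annual")

new_crf <- function(pollutant, cause, beta, beta_se, increment = NA_real_,
                    source_rr = NULL, model = "direct") {
  stopifnot(pollutant %in% names(POLLUTANT_METRIC), cause %in% CAUSES,
            is.finite(beta), is.finite(beta_se), beta_se >= 0)
  structure(list(pollutant = pollutant, cause = cause, beta = beta,
                 beta_se = beta_se, increment = increment,
                 source_rr = source_rr, model = model),
            class = "crf")
}

#' @export
print.crf <- function(x, ...) {
  cat(sprintf("crf [%s/%s, %s]: beta = %.5g +- %.5g per unit\n",
              x$pollutant, x$cause, x$model, x$beta, x$beta_se))
  invisible(x)
}

#' Concentration-response factor from a published relative risk
#'
#' Converts a relative risk with 95% confidence interval, reported per
#' concentration increment (typically 10 ppb or 10 ug/m3), into the slope of
#' the log-linear concentration-mortality relation:
#' `beta = ln(rr_central) / increment`, with standard error from the
#' symmetric normal log-scale interval,
#' `beta_se = ln(rr_hi / rr_lo) / (2 * 1.96 * increment)`.
#'
#' @param rr_central,rr_lo,rr_hi Central RR and 95% CI bounds; must satisfy
#'   `0 < rr_lo <= rr_central <= rr_hi`.
#' @param increment Concentration increment the RR refers to (> 0), in the
#'   pollutant metric's units.
#' @param pollutant `"o3"` or `"pm25"`.
#' @param cause Cause of death.
#' @param model Free-form model tag kept in provenance.
#' @return Object of class `crf` with elements `beta`, `beta_se` (per unit
#'   concentration), `pollutant`, `cause`, `source_rr`, `increment`.
#' @examples
#' crf_from_rr(1.04, 1.013, 1.067, 10, "o3", "respiratory")$beta # ~0.003922
#' @export
crf_from_rr <- function(rr_central, rr_lo, rr_hi, increment,
                        pollutant, cause, model = "rr") {
  if (!(rr_lo > 0 && rr_lo <= rr_central && rr_central <= rr_hi))
    stop("require 0 < rr_lo <= rr_central <= rr_hi", call. = FALSE)
  stopifnot(increment > 0)
  new_crf(pollutant, cause,
          beta = log(rr_central) / increment,
          beta_se = log(rr_hi / rr_lo) / (2 * 1.96 * increment),
          increment = increment,
          source_rr = c(central = rr_central, lo = rr_lo, hi = rr_hi),
          model = model)
}

#' Concentration-response factor given directly as a slope
#'
#' For epidemiological models reported as a slope with standard error rather
#' than an RR per increment (e.g. threshold-including fits).
#'
#' @param beta Slope per unit concentration (1/ppb or 1/(ug/m3)).
#' @param beta_se Standard error of `beta` (>= 0).
#' @inheritParams crf_from_rr
#' @return Object of class `crf`.
#' @export
crf_direct <- function(beta, beta_se, pollutant, cause, model = "direct") {
  if (beta_se < 0) stop("beta_se must be >= 0", call. = FALSE)
  new_crf(pollutant, cause, beta = beta, beta_se = beta_se, model = model)
}

#' Built-in concentration-response factor registry
#'
#' The CRF sets used by the burden estimates and the sensitivity analysis,
#' all for adults >= 30 from the long-term cohort literature:
#'
#' * `o3_multipollutant`: respiratory RR 1.04 (1.013-1.067) per 10 ppb
#'   seasonal daily 1-hr maximum O3, from the two-pollutant ACS cohort model
#'   controlling for PM2.5 (the default O3 set).
#' * `o3_singlepollutant`: respiratory RR 1.029 (1.010-1.048) per 10 ppb
#'   from the single-pollutant model (no PM2.5 control).
#' * `o3_threshold56`: respiratory slope 0.00432 +- 0.00121 per ppb from the
#'   model including a 56-ppb threshold (pair with `lct = 56`).
#' * `pm25_reanalysis`: per 10 ug/m3 annual PM2.5, all-cause RR 1.06
#'   (1.04-1.08), cardiopulmonary 1.13 (1.10-1.16), lung cancer 1.14
#'   (1.06-1.23), from the extended ACS reanalysis (the default PM2.5 set).
#' * `pm25_acs_1979_1983`: the earlier ACS estimates, all-cause 1.04
#'   (1.01-1.08), cardiopulmonary 1.06 (1.02-1.10), lung cancer 1.08
#'   (1.01-1.16).
#' * `pm25_six_cities`: the extended Harvard Six Cities estimates, all-cause
#'   1.16 (1.07-1.26), cardiovascular-as-cardiopulmonary 1.28 (1.13-1.44),
#'   lung cancer 1.27 (0.96-1.69).
#'
#' All-cause CRFs are an alternative to, never additive with, the
#' cause-specific ones.
#'
#' @param set Registry set name (see above).
#' @return Named list of `crf` objects (by cause).
#' @export
default_crf_registry <- function(set = c("o3_multipollutant",
                                         "o3_singlepollutant",
                                         "o3_threshold56",
                                         "pm25_reanalysis",
                                         "pm25_acs_1979_1983",
                                         "pm25_six_cities")) {
  set <- match.arg(set)
  switch(set,
    o3_multipollutant = list(
      respiratory = crf_from_rr(1.04, 1.013, 1.067, 10, "o3", "respiratory",
                                model = set)),
    o3_singlepollutant = list(
      respiratory = crf_from_rr(1.029, 1.010, 1.048, 10, "o3", "respiratory",
                                model = set)),
    o3_threshold56 = list(
      respiratory = crf_direct(0.00432, 0.00121, "o3", "respiratory",
                               model = set)),
    pm25_reanalysis = list(
      all_cause = crf_from_rr(1.06, 1.04, 1.08, 10, "pm25", "all_cause", set),
      cardiopulmonary = crf_from_rr(1.13, 1.10, 1.16, 10, "pm25",
                                    "cardiopulmonary", set),
      lung_cancer = crf_from_rr(1.14, 1.06, 1.23, 10, "pm25", "lung_cancer",
                                set)),
    pm25_acs_1979_1983 = list(
      all_cause = crf_from_rr(1.04, 1.01, 1.08, 10, "pm25", "all_cause", set),
      cardiopulmonary = crf_from_rr(1.06, 1.02, 1.10, 10, "pm25",
                                    "cardiopulmonary", set),
      lung_cancer = crf_from_rr(1.08, 1.01, 1.16, 10, "pm25", "lung_cancer",
                                set)),
    pm25_six_cities = list(
      all_cause = crf_from_rr(1.16, 1.07, 1.26, 10, "pm25", "all_cause", set),
      cardiopulmonary = crf_from_rr(1.28, 1.13, 1.44, 10, "pm25",
                                    "cardiopulmonary", set),
      lung_cancer = crf_from_rr(1.27, 0.96, 1.69, 10, "pm25", "lung_cancer",
                                set))
  )
}

#' Attributable fraction of baseline deaths
#'
#' `AF = (RR - 1) / RR = 1 - exp(-beta * dX)` per cell; always in `[0, 1)`
#' for `beta, dX >= 0`, increasing in both.
#'
#' @param crf A `crf`.
#' @param dx A [delta_exposure()] whose metric matches the CRF's pollutant.
#' @return A dimensionless `gridded_field`.
#' @export
attributable_fraction <- function(crf, dx) {
  stopifnot(inherits(crf, "crf"), inherits(dx, "delta_exposure"))
  if (POLLUTANT_METRIC[[crf$pollutant]] != dx$metric)
    stop(sprintf("unit mismatch: CRF is per %s but exposure metric is %s",
                 crf$pollutant, dx$metric), call. = FALSE)
  gridded_field(dx$values$grid, 1 - exp(-crf$beta * dx$values$values),
                units = "fraction")
}

#' Excess mortality attributable to the exposure increase
#'
#' Per cell, `dMort = y0 * AF * Pop` (deaths/year).
#'
#' @param af Attributable fraction `gridded_field`.
#' @param y0 Baseline mortality rate `gridded_field` (fraction/year).
#' @param pop_adult Exposed (adult) population `gridded_field`.
#' @return A `gridded_field` in deaths/year.
#' @export
excess_mortality <- function(af, y0, pop_adult) {
  stopifnot(is_gridded_field(af), is_gridded_field(y0),
            is_gridded_field(pop_adult))
  stop_if_grid_mismatch(af$grid, y0$grid)
  stop_if_grid_mismatch(af$grid, pop_adult$grid)
  gridded_field(af$grid, y0$values * af$values * pop_adult$values,
                units = "deaths/year")
}

#' Years of life lost from excess mortality
#'
#' `dYLL = dMort * YLL0` per cell.
#'
#' @param mort Excess mortality `gridded_field` (deaths/year).
#' @param yll0 Baseline years of life lost per death `gridded_field`.
#' @return A `gridded_field` in years/year.
#' @export
years_of_life_lost <- function(mort, yll0) {
  stopifnot(is_gridded_field(mort), is_gridded_field(yll0))
  stop_if_grid_mismatch(mort$grid, yll0$grid)
  gridded_field(mort$grid, mort$values * yll0$values, units = "years/year")
}

#' Burden surface for one pollutant-cause pair
#' @param mort,yll `gridded_field`s of excess mortality and YLL.
#' @param crf The `crf` used.
#' @param policy The `threshold_policy` used.
#' @return Object of class `burden_surface`.
#' @export
burden_surface <- function(mort, yll, crf, policy) {
  stopifnot(is_gridded_field(mort), is_gridded_field(yll),
            inherits(crf, "crf"), inherits(policy, "threshold_policy"))
  stop_if_grid_mismatch(mort$grid, yll$grid)
  structure(list(mort = mort, yll = yll, pollutant = crf$pollutant,
                 cause = crf$cause, crf = crf, policy = policy),
            class = "burden_surface")
}

#' @export
print.burden_surface <- function(x, ...) {
  cat(sprintf("burden_surface [%s/%s]: %.4g deaths/yr, %.4g YLL/yr\n",
              x$pollutant, x$cause, sum(x$mort$values, na.rm = TRUE),
              sum(x$yll$values, na.rm = TRUE)))
  invisible(x)
}

# normalise a policy argument to a named list(o3 = ..., pm25 = ...)
as_policy_list <- function(policy) {
  if (inherits(policy, "threshold_policy"))
    return(list(o3 = policy, pm25 = policy))
  stopifnot(is.list(policy),
            all(names(policy) %in% names(POLLUTANT_METRIC)),
            all(vapply(policy, inherits, TRUE, "threshold_policy")))
  out <- list(o3 = threshold_policy(), pm25 = threshold_policy())
  out[names(policy)] <- policy
  out
}

#' Present and preindustrial exposure surfaces of a world
#'
#' Applies the seasonal window metric to the monthly O3 bundles and PM2.5
#' reconstruction to the species bundles, for both scenarios. `run_scenario`
#' and the Monte Carlo wrapper call this once and reuse the result.
#'
#' @param world A [gen_world()] bundle (or a list with the same elements).
#' @param speciation A [speciation_config()].
#' @return Nested list `$o3$present`, `$o3$preindustrial`, `$pm25$present`,
#'   `$pm25$preindustrial` of `exposure_surface`s.
#' @export
scenario_exposures <- function(world, speciation = speciation_config()) {
  list(
    o3 = list(present = o3_season_average(world$o3_present),
              preindustrial = o3_season_average(world$o3_preindustrial)),
    pm25 = list(present = pm25_reconstruct(world$pm_present, speciation),
                preindustrial = pm25_reconstruct(world$pm_preindustrial,
                                                 speciation))
  )
}

#' Point-estimate burden scenario
#'
#' Runs the full chain exposure -> dX -> AF -> dMort -> dYLL for each
#' requested pollutant-cause pair on one world, with one threshold policy
#' per pollutant. Burdens are reported per pair and never summed across
#' pollutants by default (summing O3 and PM2.5 burdens risks double
#' counting; see [sum_burdens()]).
#'
#' @param world A [gen_world()] bundle.
#' @param crfs List of `crf` objects (e.g. concatenated
#'   [default_crf_registry()] sets).
#' @param policy A [threshold_policy()] applied to both pollutants, or a
#'   named list `list(o3 = ..., pm25 = ...)`.
#' @param speciation A [speciation_config()].
#' @param exposures Optional precomputed [scenario_exposures()] result.
#' @return Object of class `scenario_result`: `$burdens` (named
#'   `"<pollutant>_<cause>"` list of `burden_surface`s), `$exposures`,
#'   `$provenance` (full configuration echo).
#' @export
run_scenario <- function(world, crfs, policy = threshold_policy(),
                         speciation = speciation_config(),
                         exposures = NULL) {
  stopifnot(is.list(crfs), length(crfs) >= 1,
            all(vapply(crfs, inherits, TRUE, "crf")))
  policies <- as_policy_list(policy)
  if (is.null(exposures)) exposures <- scenario_exposures(world, speciation)
  pop_adult <- adult_population(world$population, world$tables, world$regions)
  burdens <- list()
  for (crf in crfs) {
    pol <- crf$pollutant
    dx <- delta_exposure(exposures[[pol]]$present,
                         exposures[[pol]]$preindustrial, policies[[pol]])
    af <- attributable_fraction(crf, dx)
    y0 <- rate_surface(world$tables, world$wmap, crf$cause, world$grid)
    mort <- excess_mortality(af, y0, pop_adult)
    yll <- years_of_life_lost(mort, yll0_surface(world$tables, world$regions,
                                                 crf$cause))
    burdens[[paste(pol, crf$cause, sep = "_")]] <-
      burden_surface(mort, yll, crf, policies[[pol]])
  }
  structure(list(
    burdens = burdens,
    exposures = exposures,
    provenance = list(
      crfs = lapply(crfs, function(x) x[c("pollutant", "cause", "beta",
                                          "beta_se", "model")]),
      policy = policies, speciation = unclass(speciation))
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario_result with", length(x$burdens), "burden surface(s):\n")
  for (b in x$burdens) print(b)
  invisible(x)
}

#' Sum burden surfaces across pollutants or causes
#'
#' Explicit opt-in aggregation. Summing O3 and PM2.5 burdens assumes their
#' mortality pathways are independent; the result carries a
#' `double_counting_warning` provenance flag to record that assumption.
#'
#' @param burdens List of `burden_surface`s on one grid.
#' @return List with `mort` and `yll` `gridded_field`s and
#'   `double_counting_warning` flag.
#' @export
sum_burdens <- function(burdens) {
  stopifnot(length(burdens) >= 1,
            all(vapply(burdens, inherits, TRUE, "burden_surface")))
  g <- burdens[[1]]$mort$grid
  mort <- matrix(0, g$n_lat, g$n_lon)
  yll <- matrix(0, g$n_lat, g$n_lon)
  for (b in burdens) {
    stop_if_grid_mismatch(g, b$mort$grid)
    mort <- mort + b$mort$values
    yll <- yll + b$yll$values
  }
  pols <- unique(vapply(burdens, `[[`, "", "pollutant"))
  list(mort = gridded_field(g, mort, "deaths/year"),
       yll = gridded_field(g, yll, "years/year"),
       double_counting_warning = length(pols) > 1)
}
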