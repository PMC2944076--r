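# Bundled reference summary tables from a published global burden
# assessment of anthropogenic O3 and PM2.5. These printed summary values
# serve as inputs: the synthetic generator targets their ranges, and the
# worked-example validations recompute exposure increases, sensitivity
# percent changes, and YLL-per-death ratios from them. The package never
# uses them as outputs.

#' Reference regional exposure and demography summary
#'
#' Population-weighted average and grid-cell range of the seasonal (6-month)
#' daily 1-hr maximum O3 (ppb) and annual-mean PM2.5 (ug/m3) for the
#' preindustrial (1860) and present-day (2000) scenarios, plus the adult
#' (>= 30) population in billions, by region and for the world.
#'
#' @return Data frame, one row per region plus `"World"`.
#' @export
reference_exposure_summary <- function() {
  data.frame(
    region = c(region_names(), "World"),
    pop30_billion = c(0.28, 0.27, 0.44, 1.8, 0.15, 0.02, 2.9),
    o3_1860_avg = c(23.32, 21.42, 18.26, 18.91, 18.44, 13.37, 19.61),
    o3_1860_min = c(11.4, 12.5, 15.2, 6.15, 12.2, 3.74, 3.74),
    o3_1860_max = c(31.9, 32.3, 27.5, 35.9, 35.8, 22.8, 35.9),
    o3_2000_avg = c(54.46, 59.75, 48.92, 59.64, 44.59, 26.75, 56.70),
    o3_2000_min = c(20.2, 27.0, 32.3, 10.8, 22.3, 6.41, 6.41),
    o3_2000_max = c(71.5, 89.3, 74.3, 83.7, 90.3, 44.4, 90.3),
    pm_1860_avg = c(0.92, 1.50, 0.93, 1.19, 1.00, 0.96, 1.13),
    pm_1860_min = c(0.28, 0.14, 0.11, 0.23, 0.33, 0.22, 0.11),
    pm_1860_max = c(3.19, 4.65, 2.96, 3.06, 3.89, 2.27, 3.89),
    pm_2000_avg = c(7.50, 8.44, 14.77, 20.41, 6.35, 2.59, 16.11),
    pm_2000_min = c(0.50, 0.31, 0.40, 0.34, 0.40, 0.25, 0.25),
    pm_2000_max = c(13.9, 16.6, 39.0, 55.9, 13.9, 5.01, 55.9)
  )
}

#' Reference regional burden tables
#'
#' Published regional annual excess mortality and years of life lost
#' (thousands, mean and 1 SD) for anthropogenic O3 (respiratory) and PM2.5
#' (cardiopulmonary, lung cancer), under the natural-background
#' counterfactual (`"background"`) and under the low-concentration
#' thresholds 33.3 ppb / 5.8 ug/m3 (`"threshold"`).
#'
#' @return Data frame with columns `region`, `scenario`, `pair`, `mort`,
#'   `mort_sd`, `yll`, `yll_sd` (all in thousands).
#' @export
reference_burden_tables <- function() {
  reg <- c(region_names(), "World")
  build <- function(pair, scenario, mort, mort_sd, yll, yll_sd) {
    data.frame(region = reg, scenario = scenario, pair = pair,
               mort = mort, mort_sd = mort_sd, yll = yll, yll_sd = yll_sd)
  }
  rbind(
    build("o3_respiratory", "background",
          c(63, 35, 41, 543, 18, 1, 700), c(34, 17, 21, 253, 9, 1, 335),
          c(901, 285, 243, 4322, 137, 7, 6251),
          c(486, 138, 125, 2014, 68, 7, 2992)),
    build("o3_respiratory", "threshold",
          c(45, 25, 23, 370, 8, 0, 470), c(30, 15, 17, 220, 6, 0, 288),
          c(644, 203, 136, 2945, 61, 0, 4197),
          c(429, 122, 101, 1751, 46, 0, 2572)),
    build("pm25_cardiopulmonary", "background",
          c(154, 124, 586, 2584, 48, 2, 3499),
          c(44, 37, 149, 618, 15, 1, 864),
          c(1694, 804, 4336, 20620, 365, 11, 27607),
          c(484, 240, 1103, 4932, 114, 6, 6817)),
    build("pm25_cardiopulmonary", "threshold",
          c(52, 65, 383, 1991, 16, 0, 2506),
          c(33, 30, 143, 603, 9, 0, 816),
          c(572, 421, 2834, 15888, 122, 0, 19772),
          c(363, 194, 1058, 4812, 68, 0, 6438)),
    build("pm25_lung_cancer", "background",
          c(3, 17, 47, 152, 2, 0, 222), c(1, 7, 17, 53, 1, 0, 80),
          c(40, 152, 472, 1594, 19, 0, 2169),
          c(13, 62, 171, 556, 10, 0, 782)),
    build("pm25_lung_cancer", "threshold",
          c(1, 10, 31, 122, 1, 0, 164), c(1, 5, 14, 47, 1, 0, 68),
          c(13, 89, 311, 1280, 10, 0, 1602),
          c(13, 45, 141, 493, 10, 0, 664))
  )
}

#' Reference global sensitivity tables
#'
#' Published global annual mortality totals (thousands, mean and 1 SD) under
#' alternative concentration-response functions and threshold assumptions,
#' against which every sensitivity percent change is recomputed. Baselines
#' are the no-threshold multipollutant O3 estimate (`o3`, cause
#' `respiratory`) and the no-threshold extended-reanalysis PM2.5 estimates
#' (`pm25`, by cause).
#'
#' @return Data frame with columns `pollutant`, `scenario`, `cause`,
#'   `mort`, `mort_sd`, `is_baseline`.
#' @export
reference_sensitivity_tables <- function() {
  o3 <- data.frame(
    pollutant = "o3",
    scenario = c("multipollutant", "multipollutant_lct25",
                 "multipollutant_lct33.3", "singlepollutant",
                 "singlepollutant_lct25", "singlepollutant_lct33.3",
                 "threshold_model_lct56",
                 "singlepollutant", "singlepollutant_lct25",
                 "singlepollutant_lct33.3"),
    cause = c(rep("respiratory", 7), rep("cardiopulmonary", 3)),
    mort = c(700, 605, 470, 524, 452, 350, 178, 1076, 925, 705),
    mort_sd = c(335, 317, 288, 252, 238, 215, 187, 493, 467, 423),
    is_baseline = c(TRUE, rep(FALSE, 9))
  )
  pm <- expand.grid(cause = c("all_cause", "cardiopulmonary", "lung_cancer"),
                    scenario = c("reanalysis", "reanalysis_lct5.8",
                                 "reanalysis_lct7.5", "reanalysis_hct30",
                                 "reanalysis_hct50", "acs_1979_1983",
                                 "six_cities"),
                    stringsAsFactors = FALSE)
  pm$pollutant <- "pm25"
  pm$mort <- c(3381, 3499, 222,
               2378, 2506, 164,
               2077, 2201, 146,
               3059, 3205, 201,
               3338, 3464, 219,
               2333, 1800, 139,
               7714, 4549, 336)
  pm$mort_sd <- c(986, 864, 80,
                  876, 816, 68,
                  822, 780, 64,
                  774, 676, 68,
                  940, 826, 78,
                  1196, 742, 72,
                  2736, 1439, 198)
  pm$is_baseline <- pm$scenario == "reanalysis"
  rbind(o3, pm[, names(o3)])
}

#' Recompute the sensitivity percent changes from the reference totals
#'
#' For each non-baseline scenario, [percent_change()] of its global total
#' against the matching no-threshold baseline of the same pollutant and
#' cause. Reproducing the published parenthesised percentages pins down the
#' percent-change convention (unrounded totals, half-away-from-zero
#' rounding to 0.1).
#'
#' @return The sensitivity table with an added `pct_change` column
#'   (`NA` for baselines).
#' @export
reference_percent_changes <- function() {
  tab <- reference_sensitivity_tables()
  base <- tab[tab$is_baseline, c("pollutant", "cause", "mort")]
  names(base)[3] <- "baseline"
  tab$baseline <- base$baseline[match(paste(tab$pollutant, tab$cause),
                                      paste(base$pollutant, base$cause))]
  # no percent change where no same-cause baseline exists (e.g. the O3
  # single-pollutant cardiopulmonary column)
  has <- !tab$is_baseline & !is.na(tab$baseline)
  tab$pct_change <- NA_real_
  tab$pct_change[has] <- percent_change(tab$mort[has], tab$baseline[has])
  tab
}
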