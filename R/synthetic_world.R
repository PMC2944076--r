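# Synthetic world generator.
#
# Emulates the statistical structure of the real pipeline inputs — gridded
# chemical-transport-model concentration fields for a present-day and a
# preindustrial scenario, a population surface clustered in hotspots that
# co-locate with pollution plumes, countries grown on a synthetic land mask,
# and region-structured vital-statistics tables — so that every downstream
# stage is exercised without any external data. It makes no attempt to
# emulate atmospheric chemistry or real spatial patterns beyond these
# summary properties.

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed for independent generator streams (< 2^31)
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.numeric(seed) * 1009 + h * 97) %% 2147483549
}

# smooth random surface in [0, 1]: iid normals on a coarse grid, bilinearly
# interpolated to the full grid with longitudinal wrap-around
smooth_field <- function(grid, n_coarse_lat = 6, n_coarse_lon = 12) {
  C <- matrix(stats::rnorm(n_coarse_lat * n_coarse_lon),
              n_coarse_lat, n_coarse_lon)
  u <- (grid$lat + 90) / 180 * n_coarse_lat + 0.5   # continuous coarse coords
  v <- (grid$lon + 180) / 360 * n_coarse_lon + 0.5
  i0 <- pmin(pmax(floor(u), 1), n_coarse_lat); i1 <- pmin(i0 + 1, n_coarse_lat)
  fu <- pmin(pmax(u - i0, 0), 1)
  j0 <- ((floor(v) - 1) %% n_coarse_lon) + 1
  j1 <- (j0 %% n_coarse_lon) + 1
  fv <- v - floor(v)
  out <- matrix(0, grid$n_lat, grid$n_lon)
  for (i in seq_len(grid$n_lat)) {
    a <- C[i0[i], j0] * (1 - fv) + C[i0[i], j1] * fv
    b <- C[i1[i], j0] * (1 - fv) + C[i1[i], j1] * fv
    out[i, ] <- a * (1 - fu[i]) + b * fu[i]
  }
  rng <- range(out)
  if (diff(rng) == 0) return(out * 0)
  (out - rng[1]) / diff(rng)
}

# squared angular distance (degrees^2) from every cell to one point,
# with longitude wrap and cos-latitude metric
dist2_to <- function(grid, lat0, lon0) {
  dlon <- abs(outer(rep(1, grid$n_lat), grid$lon) - lon0)
  dlon <- pmin(dlon, 360 - dlon)
  dlat <- outer(grid$lat - lat0, rep(1, grid$n_lon))
  coslat <- cos(outer((grid$lat + lat0) / 2, rep(1, grid$n_lon)) * pi / 180)
  dlat^2 + (dlon * coslat)^2
}

#' Synthetic world configuration
#'
#' Defaults describe a present-day (year-2000-like) world: a 64 x 128 (~2.8
#' degree) grid, 6.6 billion people, population-weighted present O3 in the
#' tens of ppb with grid-cell range about 6.4-90.3 ppb, present PM2.5 range
#' about 0.25-55.9 ug/m3, and preindustrial levels a small fraction of
#' present (about 0.35 for O3 and 0.07 for PM2.5, matching the global
#' population-weighted preindustrial/present ratios of the simulated
#' concentration record the generator emulates).
#'
#' @param seed Integer RNG seed; every generated surface is a pure function
#'   of `(config, seed)`.
#' @param n_lat,n_lon Grid dimensions (see [make_grid()]).
#' @param n_countries Number of countries to grow on land (>= 6).
#' @param total_population Global population (persons); the generated
#'   surface sums to this exactly.
#' @param pollution_hotspot_count Number of population/pollution hotspots.
#' @param o3_range_present,pm_range_present Target (min, max) of the
#'   present-day annual-mean surfaces, ppb and ug/m3.
#' @param preindustrial_scale Named fractions `c(o3 = ..., pm25 = ...)` in
#'   `[0, 1)`: preindustrial = scale x the shared background component (no
#'   anthropogenic plumes).
#' @param land_fraction Fraction of cells that are land.
#' @param unavailable_fraction Fraction of countries flagged as lacking
#'   country-specific mortality rates (exercises the regional fallback).
#' @param pm_composition Species mass shares (percent or any non-negative
#'   weights) in order `oc, bc, no3, so4`.
#' @param violation_cells Number of cells where the preindustrial
#'   concentration is deliberately raised above present, to exercise the
#'   delta clamp (default 0).
#' @param seasonal_amplitude Relative amplitude of the O3 seasonal cycle.
#' @param noise_sd Relative multiplicative noise on monthly O3.
#' @return Object of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(seed = 1L,
                                   n_lat = 64L, n_lon = 128L,
                                   n_countries = 60L,
                                   total_population = 6.6e9,
                                   pollution_hotspot_count = 40L,
                                   o3_range_present = c(6.41, 90.3),
                                   pm_range_present = c(0.25, 55.9),
                                   preindustrial_scale = c(o3 = 0.45,
                                                           pm25 = 0.08),
                                   land_fraction = 0.3,
                                   unavailable_fraction = 0.25,
                                   pm_composition = c(oc = 45.6, bc = 9.1,
                                                      no3 = 4.9, so4 = 40.4),
                                   violation_cells = 0L,
                                   seasonal_amplitude = 0.3,
                                   noise_sd = 0.02) {
  stopifnot(o3_range_present[1] < o3_range_present[2],
            pm_range_present[1] < pm_range_present[2],
            all(preindustrial_scale >= 0 & preindustrial_scale < 1),
            all(c("o3", "pm25") %in% names(preindustrial_scale)),
            land_fraction > 0 && land_fraction < 1,
            unavailable_fraction >= 0 && unavailable_fraction <= 1,
            n_countries >= 6, total_population > 0,
            pollution_hotspot_count >= 1,
            all(pm_composition >= 0), sum(pm_composition) > 0,
            seasonal_amplitude >= 0 && seasonal_amplitude < 1,
            noise_sd >= 0, violation_cells >= 0)
  structure(as.list(environment()), class = "synthetic_world_config")
}

#' Monthly O3 bundle with a hemispheric seasonal cycle
#'
#' Builds 12 monthly fields of the daily 1-hr maximum O3 mean:
#' `month_m = annual * (1 + amplitude * cos(2*pi*(m - peak)/12)) * noise`,
#' where the peak month is `hemispheric_phase` in the northern hemisphere
#' and offset by 6 months in the southern hemisphere, so that the 6-month
#' window search is exercised with wrap-around windows south of the equator.
#'
#' @param grid A `grid_spec`.
#' @param hemispheric_phase Peak month (1-12) in the northern hemisphere;
#'   default 7 (July).
#' @param seed RNG seed for the annual surface and noise.
#' @param annual Optional annual-mean `gridded_field` (ppb); generated from
#'   a smooth random surface scaled into `range` when omitted.
#' @param range Target (min, max) for a generated annual surface.
#' @param amplitude Relative seasonal amplitude in `[0, 1)`.
#' @param noise_sd Relative SD of multiplicative month-to-month noise; 0
#'   gives an exactly phase-symmetric cycle.
#' @return List of 12 `gridded_field`s (January..December).
#' @export
gen_o3_monthly <- function(grid, hemispheric_phase = 7, seed = 1,
                           annual = NULL, range = c(6.41, 90.3),
                           amplitude = 0.3, noise_sd = 0.02) {
  stopifnot(is_grid_spec(grid), hemispheric_phase %in% 1:12,
            amplitude >= 0 && amplitude < 1, noise_sd >= 0)
  with_seed(sub_seed(seed, "o3_monthly"), {
    if (is.null(annual)) {
      s <- smooth_field(grid)
      annual <- gridded_field(grid, range[1] + diff(range) * s, units = "ppb")
    }
    stop_if_grid_mismatch(grid, annual$grid)
    peak <- matrix(hemispheric_phase, grid$n_lat, grid$n_lon)
    peak[grid$lat < 0, ] <- (hemispheric_phase + 6 - 1) %% 12 + 1
    lapply(1:12, function(m) {
      # phase distance in months, folded to [0, 6] so the cycle is exactly
      # symmetric around the peak and exactly periodic in the phase
      off <- (m - peak) %% 12
      off <- pmin(off, 12 - off)
      season <- 1 + amplitude * cos(2 * pi * off / 12)
      noise <- if (noise_sd > 0)
        matrix(pmax(0, 1 + stats::rnorm(grid$n_lat * grid$n_lon, 0, noise_sd)),
               grid$n_lat, grid$n_lon)
      else 1
      gridded_field(grid, annual$values * season * noise, units = annual$units)
    })
  })
}

#' Speciated PM2.5 bundle with a target composition
#'
#' Splits a total PM2.5 mass surface into `so4`, `no3`, `bc`, `oc` species
#' whose global mean mass shares match `composition_weights` (normalised)
#' within 1%; per-cell shares vary smoothly around the target. The `nh4`
#' surface is derived stoichiometrically as the ammonium required for full
#' neutralisation of sulfate and nitrate.
#'
#' @param grid A `grid_spec`.
#' @param composition_weights Non-negative weights in order
#'   `c(oc, bc, no3, so4)` (any scale; normalised internally).
#' @param seed RNG seed.
#' @param total Optional total-mass `gridded_field` (ug/m3); generated from
#'   a smooth random surface scaled into `range` when omitted.
#' @param range Target (min, max) for a generated total surface.
#' @return Named list of `gridded_field`s `so4, no3, nh4, bc, oc`.
#' @export
gen_pm_species <- function(grid, composition_weights = c(oc = 45.6, bc = 9.1,
                                                         no3 = 4.9,
                                                         so4 = 40.4),
                           seed = 1, total = NULL, range = c(0.25, 55.9)) {
  stopifnot(is_grid_spec(grid), all(composition_weights >= 0))
  if (sum(composition_weights) <= 0)
    stop("composition weights must not be all zero", call. = FALSE)
  w <- composition_weights / sum(composition_weights)
  names(w) <- c("oc", "bc", "no3", "so4")
  with_seed(sub_seed(seed, "pm_species"), {
    if (is.null(total)) {
      s <- smooth_field(grid)
      total <- gridded_field(grid, range[1] + diff(range) * s, units = "ug/m3")
    }
    stop_if_grid_mismatch(grid, total$grid)
    # smooth +-5% perturbations of the shares, renormalised per cell
    raw <- lapply(names(w), function(nm) {
      if (w[[nm]] == 0) return(matrix(0, grid$n_lat, grid$n_lon))
      w[[nm]] * (1 + 0.05 * (2 * smooth_field(grid) - 1))
    })
    names(raw) <- names(w)
    denom <- Reduce(`+`, raw)
    species <- lapply(raw, function(r) r / denom * total$values)
    cfg <- speciation_config()
    out <- list(
      so4 = species$so4, no3 = species$no3,
      nh4 = (cfg$sulfate_salt_factor - 1) * species$so4 +
            (cfg$nitrate_salt_factor - 1) * species$no3,
      bc = species$bc, oc = species$oc
    )
    lapply(out, function(v) gridded_field(grid, v, units = total$units))
  })
}

#' Region-structured synthetic vital-statistics tables
#'
#' Draws country baseline mortality rates around their region's default
#' (log-normal jitter, SD about 20%), regional adult fractions around the
#' global value of 0.439, and regional YLL0 around the global-average
#' defaults returned by [yll0_defaults()]; a configurable fraction of
#' countries is flagged "rate unavailable" so the regional-fallback path is
#' exercised.
#'
#' @param country_regions Data frame with columns `country_code`,
#'   `region_id` mapping each country to a region in [region_names()].
#' @param seed RNG seed.
#' @param unavailable_fraction Fraction of countries (per cause) flagged as
#'   lacking a country-specific rate.
#' @return A [demography_tables()].
#' @export
gen_demography <- function(country_regions, seed = 1,
                           unavailable_fraction = 0.25) {
  stopifnot(is.data.frame(country_regions),
            all(c("country_code", "region_id") %in% names(country_regions)),
            all(country_regions$region_id %in% region_names()))
  with_seed(sub_seed(seed, "demography"), {
    rates <- region_rate_defaults()
    yll0 <- yll0_defaults()
    reg_rows <- do.call(rbind, lapply(region_names(), function(rg) {
      frac <- 0.439 * exp(stats::runif(1, -0.07, 0.07))
      do.call(rbind, lapply(names(yll0), function(cz) {
        data.frame(region_id = rg, cause = cz,
                   rate = rates[rates$region_id == rg, cz],
                   fraction_30plus = frac,
                   yll0 = yll0[[cz]] * exp(stats::runif(1, -0.15, 0.15)))
      }))
    }))
    cc <- country_regions
    country_rows <- do.call(rbind, lapply(names(yll0), function(cz) {
      base <- rates[match(cc$region_id, rates$region_id), cz]
      data.frame(
        country_code = cc$country_code, region_id = cc$region_id, cause = cz,
        rate = pmin(0.1, base * exp(stats::rnorm(nrow(cc), 0, 0.2))),
        available = stats::runif(nrow(cc)) >= unavailable_fraction
      )
    }))
    demography_tables(country_rows, reg_rows)
  })
}

#' Default regional baseline mortality rates
#'
#' Regional adult (>= 30) baseline mortality rates, fraction/year, for the
#' six reporting regions; cause-specific values follow the regional
#' vital-statistics summary the generator emulates (world averages about
#' 0.00134 respiratory, 0.00754 cardiopulmonary, 0.00042 lung cancer per
#' year); all-cause rates are plausible adult crude rates chosen for the
#' synthetic tables.
#'
#' @return Data frame with columns `region_id`, one column per cause.
#' @export
region_rate_defaults <- function() {
  data.frame(
    region_id = region_names(),
    respiratory     = c(0.206, 0.081, 0.127, 0.171, 0.121, 0.074) / 100,
    cardiopulmonary = c(0.739, 0.502, 1.22, 0.746, 0.515, 0.346) / 100,
    lung_cancer     = c(0.011, 0.071, 0.056, 0.037, 0.025, 0.035) / 100,
    all_cause       = c(1.60, 1.00, 1.80, 1.30, 1.00, 0.90) / 100
  )
}

#' Default baseline years of life lost per death
#'
#' Global-average YLL per death by cause (3% discounting, non-uniform age
#' weights folded into the tabulated values): 7.89 cardiopulmonary, 9.77
#' respiratory, 8.93 lung cancer; all-cause set to the cardiopulmonary value
#' (cardiopulmonary deaths dominate the all-cause burden).
#'
#' @return Named numeric vector by cause.
#' @export
yll0_defaults <- function() {
  c(respiratory = 9.77, cardiopulmonary = 7.89, lung_cancer = 8.93,
    all_cause = 7.89)
}

# grow countries by multi-source breadth-first flood fill on land cells;
# returns integer country id per cell (0 = ocean)
flood_fill_countries <- function(grid, land, seeds) {
  owner <- matrix(0L, grid$n_lat, grid$n_lon)
  owner[seeds] <- seq_along(seeds)
  queue <- seeds
  nlat <- grid$n_lat; nlon <- grid$n_lon
  while (length(queue)) {
    nxt <- integer(0)
    for (f in queue) {
      i <- (f - 1L) %% nlat + 1L
      j <- (f - 1L) %/% nlat + 1L
      cand <- c(
        if (i > 1L) f - 1L,
        if (i < nlat) f + 1L,
        ((j - 2L) %% nlon) * nlat + i,   # west, wrapped
        (j %% nlon) * nlat + i           # east, wrapped
      )
      cand <- cand[land[cand] & owner[cand] == 0L]
      owner[cand] <- owner[f]
      nxt <- c(nxt, cand)
    }
    queue <- unique(nxt)
  }
  # land components containing no seed: assign to the nearest seed
  orphan <- which(land & owner == 0L)
  if (length(orphan)) {
    o_lat <- grid$lat[(orphan - 1L) %% grid$n_lat + 1L]
    o_lon <- grid$lon[(orphan - 1L) %/% grid$n_lat + 1L]
    s_lat <- grid$lat[(seeds - 1L) %% grid$n_lat + 1L]
    s_lon <- grid$lon[(seeds - 1L) %/% grid$n_lat + 1L]
    for (k in seq_along(orphan)) {
      dlon <- abs(s_lon - o_lon[k]); dlon <- pmin(dlon, 360 - dlon)
      d2 <- (s_lat - o_lat[k])^2 +
        (dlon * cos((s_lat + o_lat[k]) / 2 * pi / 180))^2
      owner[orphan[k]] <- which.min(d2)
    }
  }
  owner
}

#' Generate a complete synthetic world
#'
#' Produces, under one seed, everything the burden pipeline consumes: the
#' grid; a synthetic land mask (threshold on a smooth noise surface);
#' countries grown by seeded flood fill on land, with half/half fractional
#' cell-to-country weights on internal borders; six continental regions from
#' clustered country seeds; a population surface built from log-normal
#' hotspots; vital-statistics tables via [gen_demography()]; and present /
#' preindustrial concentration bundles in which the present-day field is a
#' shared smooth background plus anthropogenic plumes co-located with the
#' population hotspots, while the preindustrial field is
#' `preindustrial_scale` times the background component only — so present >=
#' preindustrial everywhere by construction (unless `violation_cells`
#' injects exceptions), and population co-locates with pollution.
#'
#' @param config A [synthetic_world_config()].
#' @return Object of class `synthetic_world`: `grid`, `land`, `regions`
#'   ([region_map()]), `wmap` ([country_weight_map()]), `population`,
#'   `tables`, `o3_present`/`o3_preindustrial` (12-month bundles),
#'   `pm_present`/`pm_preindustrial` (species bundles), `config`.
#' @export
gen_world <- function(config = synthetic_world_config()) {
  stopifnot(inherits(config, "synthetic_world_config"))
  grid <- make_grid(config$n_lat, config$n_lon)
  ncell <- grid$n_lat * grid$n_lon
  with_seed(config$seed, {
    # --- land mask ---
    land_f <- smooth_field(grid, 8, 16)
    land <- land_f >= stats::quantile(land_f, 1 - config$land_fraction)
    n_land <- sum(land)
    if (config$n_countries > n_land)
      stop("config error: n_countries exceeds land cell count", call. = FALSE)

    # --- countries and regions ---
    land_idx <- which(land)
    seeds <- sample(land_idx, config$n_countries)
    owner <- flood_fill_countries(grid, land, seeds)
    seed_lat <- grid$lat[(seeds - 1) %% grid$n_lat + 1]
    seed_lon <- grid$lon[(seeds - 1) %/% grid$n_lat + 1]
    # six contiguous-ish region groups from the country seed locations
    # (complete-linkage clustering; deterministic)
    hc <- stats::hclust(stats::dist(cbind(seed_lat, seed_lon / 2)),
                        method = "complete")
    country_region <- region_names()[stats::cutree(hc, k = 6)]
    region <- matrix(NA_character_, grid$n_lat, grid$n_lon)
    region[land] <- country_region[owner[land]]
    regions <- region_map(grid, region)

    # --- cell-to-country weights: split border cells half/half ---
    codes <- sprintf("C%03d", seq_len(config$n_countries))
    wrows <- vector("list", n_land)
    nlat <- grid$n_lat; nlon <- grid$n_lon
    for (k in seq_len(n_land)) {
      f <- land_idx[k]
      i <- (f - 1L) %% nlat + 1L
      j <- (f - 1L) %/% nlat + 1L
      own <- owner[f]
      nb <- c(if (i > 1L) f - 1L, if (i < nlat) f + 1L,
              ((j - 2L) %% nlon) * nlat + i, (j %% nlon) * nlat + i)
      other <- setdiff(unique(owner[nb][land[nb]]), own)
      ci <- cell_index(grid, i, j)
      wrows[[k]] <- if (length(other)) {
        data.frame(cell_index = ci, country_code = codes[c(own, other[1])],
                   weight = c(0.5, 0.5))
      } else {
        data.frame(cell_index = ci, country_code = codes[own], weight = 1)
      }
    }
    wmap <- country_weight_map(do.call(rbind, wrows))

    # --- population: log-normal hotspots on land ---
    n_hot <- config$pollution_hotspot_count
    hot <- sample(land_idx, min(n_hot, n_land), replace = FALSE)
    hot_lat <- grid$lat[(hot - 1) %% nlat + 1]
    hot_lon <- grid$lon[(hot - 1) %/% nlat + 1]
    amp <- stats::rlnorm(length(hot), 0, 1)
    sigma <- stats::runif(length(hot), 3, 8)
    pop <- matrix(0, nlat, nlon)
    plume_broad <- matrix(0, nlat, nlon)   # O3-like: long atmospheric lifetime
    plume_narrow <- matrix(0, nlat, nlon)  # PM-like: short lifetime, localised
    for (h in seq_along(hot)) {
      d2 <- dist2_to(grid, hot_lat[h], hot_lon[h])
      pop <- pop + amp[h] * exp(-d2 / (2 * sigma[h]^2))
      plume_broad <- plume_broad + amp[h] * exp(-d2 / (2 * sigma[h]^2))
      plume_narrow <- plume_narrow + amp[h] * exp(-d2 / (2 * (0.6 * sigma[h])^2))
    }
    pop[!land] <- 0
    pop <- pop + land * 0.005 * max(pop)   # thin rural base
    pop <- pop / sum(pop) * config$total_population
    population <- gridded_field(grid, pop, units = "persons")
    plume_broad <- plume_broad / max(plume_broad)
    plume_narrow <- plume_narrow / max(plume_narrow)

    # --- concentration fields ---
    # present = scaled(background + plume); preindustrial = scale * scaled
    # background component only, so present >= preindustrial cell-wise
    build_pair <- function(range, pre_scale, plume, plume_weight = 1.2) {
      bg <- smooth_field(grid)
      raw_present <- bg + plume_weight * plume
      s <- function(x) range[1] + diff(range) * x / max(raw_present)
      list(present = s(raw_present), pre = pre_scale * s(bg))
    }
    # the configured O3 range describes the seasonal-window metric; divide
    # out the best-window seasonal enhancement so the derived metric, not
    # the annual mean, spans the range
    season_gain <- 1 + 0.644 * config$seasonal_amplitude
    o3_pair <- build_pair(config$o3_range_present / season_gain,
                          config$preindustrial_scale[["o3"]], plume_broad)
    # the configured PM range describes reconstructed PM2.5 mass; divide out
    # the mean speciation gain so raw species masses scale to match
    spc <- speciation_config()
    wc <- config$pm_composition / sum(config$pm_composition)
    pm_gain <- spc$oc_multiplier * wc[[1]] + wc[[2]] +
      spc$nitrate_salt_factor * wc[[3]] + spc$sulfate_salt_factor * wc[[4]]
    pm_pair <- build_pair(config$pm_range_present / pm_gain,
                          config$preindustrial_scale[["pm25"]], plume_narrow,
                          plume_weight = 2)

    if (config$violation_cells > 0) {
      v <- sample(land_idx, min(config$violation_cells, n_land))
      o3_pair$pre[v] <- o3_pair$present[v] * 1.2
      pm_pair$pre[v] <- pm_pair$present[v] * 1.2
    }

    o3_present <- gen_o3_monthly(
      grid, hemispheric_phase = 7, seed = config$seed,
      annual = gridded_field(grid, o3_pair$present, units = "ppb"),
      amplitude = config$seasonal_amplitude, noise_sd = config$noise_sd)
    # preindustrial cycle: same phase and amplitude, no extra noise, so the
    # monthly ordering present >= preindustrial is preserved
    o3_preindustrial <- gen_o3_monthly(
      grid, hemispheric_phase = 7, seed = config$seed,
      annual = gridded_field(grid, o3_pair$pre, units = "ppb"),
      amplitude = config$seasonal_amplitude, noise_sd = 0)

    pm_present <- gen_pm_species(grid, config$pm_composition,
                                 seed = config$seed,
                                 total = gridded_field(grid, pm_pair$present,
                                                       units = "ug/m3"))
    pm_preindustrial <- gen_pm_species(grid, config$pm_composition,
                                       seed = config$seed,
                                       total = gridded_field(grid, pm_pair$pre,
                                                             units = "ug/m3"))

    tables <- gen_demography(
      data.frame(country_code = codes, region_id = country_region),
      seed = config$seed,
      unavailable_fraction = config$unavailable_fraction)

    structure(list(grid = grid, land = land, regions = regions, wmap = wmap,
                   population = population, tables = tables,
                   o3_present = o3_present,
                   o3_preindustrial = o3_preindustrial,
                   pm_present = pm_present,
                   pm_preindustrial = pm_preindustrial,
                   config = config),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %dx%d grid, %d land cells, %d countries, pop %.3g\n",
              x$grid$n_lat, x$grid$n_lon, sum(x$land),
              x$config$n_countries, sum(x$population$values)))
  invisible(x)
}

#' Write a synthetic world to a directory of text files
#'
#' Writes the concentration bundles via [write_field()] and the tables via
#' the CSV writers, producing the on-disk layout consumed by a file-based
#' run: `o3_present.txt`, `o3_preindustrial.txt`, `pm_<species>_present.txt`
#' and `_preindustrial.txt`, `population.txt`, `regions_map.csv`,
#' `countries.csv`, `regions.csv`, `weights.csv`.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_field(world$o3_present, p("o3_present.txt"))
  write_field(world$o3_preindustrial, p("o3_preindustrial.txt"))
  for (sp in names(world$pm_present)) {
    write_field(world$pm_present[[sp]], p(sprintf("pm_%s_present.txt", sp)))
    write_field(world$pm_preindustrial[[sp]],
                p(sprintf("pm_%s_preindustrial.txt", sp)))
  }
  write_field(world$population, p("population.txt"))
  utils::write.csv(
    data.frame(cell_index = cell_index(
                 world$grid,
                 rep(seq_len(world$grid$n_lat), each = world$grid$n_lon),
                 rep(seq_len(world$grid$n_lon), times = world$grid$n_lat)),
               region_id = as.vector(t(world$regions$region))),
    p("regions_map.csv"), row.names = FALSE, na = "")
  write_demography_tables(world$tables, p("countries.csv"), p("regions.csv"))
  write_country_weights(world$wmap, p("weights.csv"))
  invisible(dir)
}
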