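# Monte Carlo propagation of concentration-response and concentration
# uncertainty to burden standard deviations.
#
# Each draw samples a concentration-response slope from N(beta, beta_se^2)
# and perturbs the present-day exposure surface by a multiplicative normal
# factor with SD = conc_sd_fraction (25% by default), then reruns the burden
# chain. Regional SDs are computed from draw-level regional sums, preserving
# within-draw spatial covariance. The preindustrial surface is never
# perturbed.

#' Monte Carlo configuration
#'
#' @param n_draws Number of Monte Carlo draws (>= 2; default 500).
#' @param conc_sd_fraction SD of the multiplicative present-day
#'   concentration perturbation, as a fraction of the simulated value
#'   (default 0.25).
#' @param conc_mode `"correlated"` (default): one N(1, sd^2) factor per draw
#'   applied to every cell, treating the concentration uncertainty as a
#'   model-wide bias; `"independent"`: an independent factor per cell.
#' @param seed Integer seed; identical configurations give bit-identical
#'   results.
#' @param truncate_negative Truncate negative slope draws and concentration
#'   factors at 0 (default `TRUE`).
#' @param keep_draws Retain the draw-level regional sums in the result.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_draws = 500L, conc_sd_fraction = 0.25,
                      conc_mode = c("correlated", "independent"),
                      seed = 1L, truncate_negative = TRUE,
                      keep_draws = FALSE) {
  conc_mode <- match.arg(conc_mode)
  if (n_draws < 2) stop("config error: n_draws must be >= 2", call. = FALSE)
  stopifnot(conc_sd_fraction >= 0)
  structure(list(n_draws = as.integer(n_draws),
                 conc_sd_fraction = conc_sd_fraction,
                 conc_mode = conc_mode, seed = seed,
                 truncate_negative = truncate_negative,
                 keep_draws = keep_draws),
            class = "mc_config")
}

#' Sample concentration-response slopes
#'
#' `n_draws` draws from `N(beta, beta_se^2)`, truncated at 0 when
#' `truncate_negative` is set; deterministic for a given configuration and
#' CRF (each CRF has its own substream).
#'
#' @param crf A `crf`.
#' @param cfg An [mc_config()].
#' @return Numeric vector of length `n_draws`.
#' @export
draw_betas <- function(crf, cfg) {
  stopifnot(inherits(crf, "crf"), inherits(cfg, "mc_config"))
  tag <- paste("beta", crf$pollutant, crf$cause, crf$model, sep = "_")
  with_seed(sub_seed(cfg$seed, tag), {
    b <- stats::rnorm(cfg$n_draws, crf$beta, crf$beta_se)
    if (cfg$truncate_negative) b <- pmax(0, b)
    b
  })
}

# multiplicative concentration factors for one draw: scalar in correlated
# mode, one per cell in independent mode; floored at 0
conc_factors <- function(cfg, metric, draw_index, ncell) {
  if (cfg$conc_sd_fraction == 0)
    return(if (cfg$conc_mode == "correlated") 1 else rep(1, ncell))
  tag <- sprintf("conc_%s_%d", metric, draw_index)
  with_seed(sub_seed(cfg$seed, tag), {
    n <- if (cfg$conc_mode == "correlated") 1L else ncell
    f <- stats::rnorm(n, 1, cfg$conc_sd_fraction)
    if (cfg$truncate_negative) f <- pmax(0, f)
    f
  })
}

#' Perturb a present-day exposure surface
#'
#' Applies the draw's multiplicative concentration factor(s) to every cell
#' of the present-day surface (results floored at 0). In correlated mode the
#' perturbed/unperturbed ratio is identical across cells within a draw.
#' Preindustrial surfaces are never perturbed.
#'
#' @param present An `exposure_surface`.
#' @param cfg An [mc_config()].
#' @param draw_index Draw number (1-based); determines the substream.
#' @return A perturbed `exposure_surface`.
#' @export
perturb_present <- function(present, cfg, draw_index) {
  stopifnot(inherits(present, "exposure_surface"), inherits(cfg, "mc_config"),
            draw_index >= 1)
  g <- present$values$grid
  f <- conc_factors(cfg, present$metric, draw_index, g$n_lat * g$n_lon)
  v <- pmax(present$values$values * matrix(f, g$n_lat, g$n_lon), 0)
  exposure_surface(present$metric,
                   gridded_field(g, v, units = present$values$units),
                   window_start = present$window_start)
}

# region sums of a cell-value vector: named vector (regions..., World)
region_sums <- function(values, region_codes, n_regions) {
  s <- numeric(n_regions)
  agg <- rowsum(values[region_codes > 0], region_codes[region_codes > 0])
  s[as.integer(rownames(agg))] <- agg[, 1]
  c(s, sum(s))
}

#' Monte Carlo burden estimate
#'
#' Runs the burden chain once per draw with a sampled concentration-response
#' slope and a perturbed present-day exposure surface (one concentration
#' perturbation per pollutant per draw, shared by that pollutant's causes),
#' and reports the point estimate together with Monte Carlo means and SDs
#' per cell, per region, and for the world. Regional statistics are formed
#' from draw-level regional sums.
#'
#' @inheritParams run_scenario
#' @param cfg An [mc_config()].
#' @return Object of class `mc_result`: `$pairs` is a named list (per
#'   `"<pollutant>_<cause>"`) holding `regional` (data frame: region,
#'   mort/yll point, mean, sd), `mort_mean`, `mort_sd`, `yll_mean`, `yll_sd`
#'   (`gridded_field`s), and optionally `draws` (draw x region matrices);
#'   `$point` is the underlying [run_scenario()] result; `$config` echoes
#'   the configuration.
#' @export
mc_burden <- function(world, crfs, policy = threshold_policy(),
                      cfg = mc_config(), speciation = speciation_config()) {
  stopifnot(inherits(cfg, "mc_config"))
  policies <- as_policy_list(policy)
  exposures <- scenario_exposures(world, speciation)
  point <- run_scenario(world, crfs, policies, speciation,
                        exposures = exposures)
  g <- world$grid
  ncell <- g$n_lat * g$n_lon
  rnames <- region_names()
  region_codes <- match(world$regions$region, rnames)
  region_codes[is.na(region_codes)] <- 0L
  pop_adult <- adult_population(world$population, world$tables, world$regions)

  # per-pollutant perturbed delta-exposure cache, filled per draw
  pair_names <- names(point$burdens)
  betas <- lapply(crfs, draw_betas, cfg = cfg)
  y0pop <- lapply(crfs, function(crf)
    rate_surface(world$tables, world$wmap, crf$cause, g)$values *
      pop_adult$values)
  yll0 <- lapply(crfs, function(crf)
    yll0_surface(world$tables, world$regions, crf$cause)$values)

  n_reg <- length(rnames)
  draws_mort <- lapply(pair_names, function(p)
    matrix(0, cfg$n_draws, n_reg + 1))
  names(draws_mort) <- pair_names
  draws_yll <- draws_mort
  sum1 <- lapply(pair_names, function(p) numeric(ncell)); names(sum1) <- pair_names
  sum2 <- sum1; ysum1 <- sum1; ysum2 <- sum1

  for (d in seq_len(cfg$n_draws)) {
    dx_by_pol <- list()
    for (pol in c("o3", "pm25")) {
      if (!any(vapply(crfs, function(x) x$pollutant == pol, TRUE))) next
      pert <- perturb_present(exposures[[pol]]$present, cfg, d)
      dx_by_pol[[pol]] <- delta_exposure(pert, exposures[[pol]]$preindustrial,
                                         policies[[pol]])$values$values
    }
    for (k in seq_along(crfs)) {
      crf <- crfs[[k]]
      pn <- pair_names[k]
      af <- 1 - exp(-betas[[k]][d] * dx_by_pol[[crf$pollutant]])
      mort <- y0pop[[k]] * af
      yll <- mort * yll0[[k]]
      draws_mort[[pn]][d, ] <- region_sums(as.vector(mort), region_codes, n_reg)
      draws_yll[[pn]][d, ] <- region_sums(as.vector(yll), region_codes, n_reg)
      sum1[[pn]] <- sum1[[pn]] + as.vector(mort)
      sum2[[pn]] <- sum2[[pn]] + as.vector(mort)^2
      ysum1[[pn]] <- ysum1[[pn]] + as.vector(yll)
      ysum2[[pn]] <- ysum2[[pn]] + as.vector(yll)^2
    }
  }

  n <- cfg$n_draws
  shape <- function(v) gridded_field(g, matrix(v, g$n_lat, g$n_lon), "",
                                     nonnegative = FALSE)
  sdev <- function(s1, s2) {
    v <- (s2 - s1^2 / n) / (n - 1)
    # cancellation guard: the one-pass formula carries O(n * eps * mean^2)
    # rounding error, so variances below that floor are numerically zero
    v[v < n * 1e-13 * (s1 / n)^2] <- 0
    sqrt(pmax(v, 0))
  }
  pairs <- list()
  for (pn in pair_names) {
    b <- point$burdens[[pn]]
    pt_mort <- region_sums(as.vector(b$mort$values), region_codes, n_reg)
    pt_yll <- region_sums(as.vector(b$yll$values), region_codes, n_reg)
    pairs[[pn]] <- list(
      regional = data.frame(
        region = c(rnames, "World"),
        mort_point = pt_mort,
        mort_mean = colMeans(draws_mort[[pn]]),
        mort_sd = apply(draws_mort[[pn]], 2, stats::sd),
        yll_point = pt_yll,
        yll_mean = colMeans(draws_yll[[pn]]),
        yll_sd = apply(draws_yll[[pn]], 2, stats::sd)
      ),
      mort_mean = shape(sum1[[pn]] / n),
      mort_sd = shape(sdev(sum1[[pn]], sum2[[pn]])),
      yll_mean = shape(ysum1[[pn]] / n),
      yll_sd = shape(sdev(ysum1[[pn]], ysum2[[pn]])),
      draws = if (cfg$keep_draws)
        list(mort = draws_mort[[pn]], yll = draws_yll[[pn]])
    )
  }
  structure(list(pairs = pairs, point = point, config = cfg),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result: %d draws, conc sd %.2f (%s)\n",
              x$config$n_draws, x$config$conc_sd_fraction,
              x$config$conc_mode))
  for (pn in names(x$pairs)) {
    w <- x$pairs[[pn]]$regional[x$pairs[[pn]]$regional$region == "World", ]
    cat(sprintf("  %s: world %.4g +- %.4g deaths/yr\n",
                pn, w$mort_mean, w$mort_sd))
  }
  invisible(x)
}
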