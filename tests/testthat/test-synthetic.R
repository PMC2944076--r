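test_that("world generation is a pure function of config and seed", {
  w1 <- gen_world(synthetic_world_config(seed = 9, n_lat = 16, n_lon = 32,
                                         n_countries = 8,
                                         pollution_hotspot_count = 10))
  w2 <- gen_world(synthetic_world_config(seed = 9, n_lat = 16, n_lon = 32,
                                         n_countries = 8,
                                         pollution_hotspot_count = 10))
  expect_identical(w1$population$values, w2$population$values)
  expect_identical(w1$pm_present$so4$values, w2$pm_present$so4$values)
  expect_identical(w1$o3_present[[3]]$values, w2$o3_present[[3]]$values)
  expect_identical(w1$tables$countries, w2$tables$countries)
  expect_identical(w1$regions$region, w2$regions$region)
})

test_that("zero preindustrial scale yields zero preindustrial fields", {
  w <- gen_world(synthetic_world_config(
    seed = 3, n_lat = 16, n_lon = 32, n_countries = 8,
    pollution_hotspot_count = 10,
    preindustrial_scale = c(o3 = 0, pm25 = 0)))
  expect_true(all(vapply(w$o3_preindustrial,
                         function(f) all(f$values == 0), TRUE)))
  expect_true(all(vapply(w$pm_preindustrial,
                         function(f) all(f$values == 0), TRUE)))
})

test_that("population is non-negative, land-only, and sums to the configured total", {
  w <- test_world()
  pop <- w$population$values
  expect_true(all(pop >= 0))
  expect_equal(sum(pop), w$config$total_population, tolerance = 1e-9)
  expect_true(all(pop[!w$land] == 0))
})

test_that("pollution co-locates with population", {
  w <- test_world()
  pm <- pm25_reconstruct(w$pm_present)$values
  expect_gt(popweighted_stats(pm, w$population)$mean, mean(pm$values))
  expect_gt(cor(w$population$values[w$land], pm$values[w$land]), 0.2)
})

test_that("present-day concentrations dominate preindustrial cell-wise", {
  w <- test_world()
  for (m in 1:12)
    expect_true(all(w$o3_present[[m]]$values >=
                      w$o3_preindustrial[[m]]$values - 1e-9))
  pm_p <- pm25_reconstruct(w$pm_present)$values$values
  pm_b <- pm25_reconstruct(w$pm_preindustrial)$values$values
  expect_true(all(pm_p >= pm_b - 1e-9))
  # ... unless violations are injected deliberately
  wv <- gen_world(synthetic_world_config(
    seed = 4, n_lat = 16, n_lon = 32, n_countries = 8,
    pollution_hotspot_count = 10, violation_cells = 5))
  vp <- pm25_reconstruct(wv$pm_present)$values$values
  vb <- pm25_reconstruct(wv$pm_preindustrial)$values$values
  expect_gt(sum(vb > vp), 0)
  d <- delta_exposure(as_pm_surface(gridded_field(wv$grid, vp)),
                      as_pm_surface(gridded_field(wv$grid, vb)))
  expect_true(all(d$values$values >= 0))
})

test_that("region map partitions land cells exactly", {
  w <- test_world()
  expect_equal(sum(!is.na(w$regions$region)), sum(w$land))
  expect_true(all(is.na(w$regions$region[!w$land])))
  expect_setequal(unique(w$regions$region[w$land]), region_names())
})

test_that("cell-to-country weights sum to one on every land cell", {
  w <- test_world()
  s <- tapply(w$wmap$weights$weight, w$wmap$weights$cell_index, sum)
  expect_true(all(abs(s - 1) < 1e-12))
  expect_equal(length(s), sum(w$land))
  # border cells carry fractional weights, so the averaging path is exercised
  expect_gt(sum(w$wmap$weights$weight < 1), 0)
})

test_that("too many countries for the land mask is a config error", {
  expect_error(gen_world(synthetic_world_config(
    seed = 1, n_lat = 8, n_lon = 16, n_countries = 120,
    pollution_hotspot_count = 4)), "land cell")
})

test_that("PM species shares track the requested composition", {
  g <- make_grid(16, 32)
  sp <- gen_pm_species(g, c(oc = 45.6, bc = 9.1, no3 = 4.9, so4 = 40.4),
                       seed = 2)
  tot <- sp$oc$values + sp$bc$values + sp$no3$values + sp$so4$values
  shares <- vapply(c("oc", "bc", "no3", "so4"),
                   function(nm) sum(sp[[nm]]$values) / sum(tot), numeric(1))
  expect_equal(unname(shares), c(45.6, 9.1, 4.9, 40.4) / 100,
               tolerance = 0.01)

  only_oc <- gen_pm_species(g, c(1, 0, 0, 0), seed = 2)
  expect_true(all(only_oc$so4$values == 0) && all(only_oc$bc$values == 0) &&
                all(only_oc$no3$values == 0) && all(only_oc$nh4$values == 0))
  expect_gt(sum(only_oc$oc$values), 0)

  doubled <- gen_pm_species(g, 2 * c(45.6, 9.1, 4.9, 40.4), seed = 2)
  expect_identical(doubled$so4$values, sp$so4$values)

  expect_error(gen_pm_species(g, c(0, 0, 0, 0)), "all zero")
})

test_that("monthly O3 cycle peaks in opposite seasons by hemisphere", {
  g <- make_grid(16, 32)
  bundle <- gen_o3_monthly(g, hemispheric_phase = 7, seed = 5, noise_sd = 0)
  s <- o3_season_average(bundle)
  north <- g$lat > 0
  # northern-hemisphere windows center on July: start month in Apr..May
  expect_true(all(s$window_start$values[north, ] %in% 4:5))
  # southern windows center on January, wrapping the year boundary
  expect_true(all(s$window_start$values[!north, ] %in% 10:11))

  shifted <- gen_o3_monthly(g, hemispheric_phase = 1, seed = 5, noise_sd = 0)
  s2 <- o3_season_average(shifted)
  expect_true(all(s2$window_start$values[north, ] %in% 10:11))
  expect_true(all(s2$window_start$values[!north, ] %in% 4:5))
  expect_equal(s2$values$values, s$values$values, tolerance = 1e-12)

  # rolling any series by 6 months shifts the winning window by exactly 6
  set.seed(55)
  for (i in 1:20) {
    x <- runif(12, 10, 80)  # random: no window ties
    rolled <- x[((seq_len(12) - 1 - 6) %% 12) + 1]
    a <- window_oracle(x)
    b <- o3_season_average(series_bundle(rolled, make_grid(2, 4)))
    expect_equal(b$window_start$values[1, 1], ((a$start - 1 + 6) %% 12) + 1)
    expect_equal(b$values$values[1, 1], a$mean, tolerance = 1e-12)
  }

  flat <- gen_o3_monthly(g, seed = 5, amplitude = 0, noise_sd = 0)
  sf <- o3_season_average(flat)
  expect_equal(sf$values$values, flat[[1]]$values, tolerance = 1e-12)
  expect_true(all(sf$window_start$values == 1))  # all windows tie -> earliest
})

test_that("synthetic demography has regional structure and exercises fallback", {
  cc <- data.frame(country_code = sprintf("C%02d", 1:30),
                   region_id = rep(region_names(), 5))
  tab <- gen_demography(cc, seed = 8, unavailable_fraction = 0)
  expect_true(all(tab$countries$available))

  tab2 <- gen_demography(cc, seed = 8, unavailable_fraction = 1)
  expect_true(all(!tab2$countries$available))
  # fallback returns the regional rate exactly
  expect_equal(resolve_rate("C01", "respiratory", tab2),
               tab2$regions$rate[tab2$regions$region_id == "Africa" &
                                   tab2$regions$cause == "respiratory"])

  # country rates jitter around regional values near the world average
  resp <- tab$countries$rate[tab$countries$cause == "respiratory"]
  expect_equal(mean(resp), 0.00134, tolerance = 0.25)
  cp <- tab$countries$rate[tab$countries$cause == "cardiopulmonary"]
  expect_equal(mean(cp), 0.00754, tolerance = 0.35)

  # YLL0 central defaults
  y <- yll0_defaults()
  expect_equal(unname(y[c("cardiopulmonary", "respiratory", "lung_cancer")]),
               c(7.89, 9.77, 8.93))
  yll_cp <- tab$regions$yll0[tab$regions$cause == "cardiopulmonary"]
  expect_true(all(abs(log(yll_cp / 7.89)) <= 0.15 + 1e-9))
})

test_that("adult population is about 44% of total under default demography", {
  w <- test_world()
  adults <- adult_population(w$population, w$tables, w$regions)
  expect_equal(sum(adults$values) / sum(w$population$values), 2.9 / 6.6,
               tolerance = 0.1)
})

test_that("a world writes to a directory of readable text artifacts", {
  w <- gen_world(synthetic_world_config(seed = 2, n_lat = 8, n_lon = 16,
                                        n_countries = 6,
                                        pollution_hotspot_count = 4))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  back <- read_field(file.path(dir, "population.txt"), grid = w$grid)
  expect_equal(back$values, w$population$values)
  tabs <- read_demography_tables(file.path(dir, "countries.csv"),
                                 file.path(dir, "regions.csv"))
  expect_equal(tabs$regions$rate, w$tables$regions$rate)
  wm <- read_country_weights(file.path(dir, "weights.csv"))
  expect_equal(sum(wm$weights$weight), sum(w$wmap$weights$weight))
})
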