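# shared fixtures, built in code and cached per session

.world_cache <- new.env(parent = emptyenv())

# moderate-size synthetic world for integration-style tests
test_world <- function(seed = 42, ...) {
  extra <- list(...)
  key <- paste0("w", seed, "_", paste(names(extra), unlist(extra),
                                      sep = "=", collapse = "_"))
  if (is.null(.world_cache[[key]])) {
    cfg <- do.call(synthetic_world_config,
                   c(list(seed = seed, n_lat = 32L, n_lon = 64L,
                          n_countries = 20L, pollution_hotspot_count = 20L),
                     extra))
    .world_cache[[key]] <- gen_world(cfg)
  }
  .world_cache[[key]]
}

default_crfs <- function() {
  c(default_crf_registry("o3_multipollutant"),
    default_crf_registry("pm25_reanalysis")[c("cardiopulmonary",
                                              "lung_cancer")])
}

# constant-valued field on a small grid
const_field <- function(value, grid = make_grid(2, 4), units = "") {
  gridded_field(grid, matrix(value, grid$n_lat, grid$n_lon), units = units)
}

# monthly O3 bundle where every cell carries the same 12-value series
series_bundle <- function(series, grid = make_grid(2, 4)) {
  stopifnot(length(series) == 12)
  lapply(series, function(v) const_field(v, grid, units = "ppb"))
}

# independent brute-force oracle for the 6-month window metric
window_oracle <- function(x) {
  means <- vapply(1:12, function(w) mean(x[((w + 0:5 - 1) %% 12) + 1]),
                  numeric(1))
  list(mean = max(means), start = which.max(means))
}

# exposure surface directly from a field (PM metric: no window bookkeeping)
as_pm_surface <- function(field) exposure_surface("pm25_annual", field)
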