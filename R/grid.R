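#' @keywords internal
"_PACKAGE"

# Authalic Earth radius, km. All cell areas use this constant.
EARTH_RADIUS_KM <- 6371

#' Regular latitude-longitude grid
#'
#' Defines a uniform cell-centered global grid. Latitude rows are ordered
#' south to north, longitudes run west to east in \[-180, 180). Cell spacing
#' is `180 / n_lat` degrees in latitude and `360 / n_lon` in longitude. Every
#' gridded surface in a pipeline run must share one `grid_spec`; mixing grids
#' is an error, never a silent regrid.
#'
#' @param n_lat,n_lon Number of latitude rows and longitude columns. Both
#'   must be even integers >= 2 (even counts keep the equator and prime
#'   meridian on cell edges).
#' @return An object of class `grid_spec` with elements `n_lat`, `n_lon`,
#'   `lat` (cell-center latitudes, increasing), `lon` (cell-center
#'   longitudes, increasing), `dlat`, `dlon` (spacings in degrees).
#' @examples
#' g <- make_grid(64, 128)
#' g$dlat # 2.8125
#' @export
make_grid <- function(n_lat, n_lon) {
  for (n in c(n_lat, n_lon)) {
    if (length(n) != 1 || !is.finite(n) || n != round(n) || n < 2 || n %% 2 != 0)
      stop("invalid grid: n_lat and n_lon must be even integers >= 2", call. = FALSE)
  }
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  dlat <- 180 / n_lat
  dlon <- 360 / n_lon
  g <- structure(
    list(
      n_lat = n_lat, n_lon = n_lon,
      lat = -90 + dlat * (seq_len(n_lat) - 0.5),
      lon = -180 + dlon * (seq_len(n_lon) - 0.5),
      dlat = dlat, dlon = dlon
    ),
    class = "grid_spec"
  )
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells (%.4f deg lat x %.4f deg lon)\n",
              x$n_lat, x$n_lon, x$dlat, x$dlon))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

#' Test whether two grids are the same
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  is_grid_spec(a) && is_grid_spec(b) && a$n_lat == b$n_lat && a$n_lon == b$n_lon
}

stop_if_grid_mismatch <- function(a, b, what = "fields") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s (%dx%d vs %dx%d)", what,
                 a$n_lat, a$n_lon, b$n_lat, b$n_lon), call. = FALSE)
  invisible(TRUE)
}

#' One scalar value per grid cell
#'
#' The universal carrier between pipeline stages: concentration, population,
#' rate, and area surfaces are all `gridded_field`s. Values are stored as an
#' `n_lat x n_lon` matrix (rows south to north); `NA` marks missing cells.
#'
#' @param grid A [make_grid()] `grid_spec`.
#' @param values Numeric matrix of dimension `n_lat x n_lon`, or a vector of
#'   length `n_lat * n_lon` in row-major order (latitude outer, longitude
#'   inner).
#' @param units Free-form units tag (e.g. `"ppb"`, `"ug/m3"`, `"km2"`,
#'   `"persons"`).
#' @param nonnegative If `TRUE` (default), negative non-missing values are an
#'   error; concentration, population, rate and area surfaces are all
#'   physically non-negative.
#' @return An object of class `gridded_field` with elements `grid`, `values`
#'   (matrix), `units`.
#' @export
gridded_field <- function(grid, values, units = "", nonnegative = TRUE) {
  stopifnot(is_grid_spec(grid))
  if (is.matrix(values)) {
    if (!all(dim(values) == c(grid$n_lat, grid$n_lon)))
      stop("values matrix must be n_lat x n_lon", call. = FALSE)
  } else {
    if (length(values) != grid$n_lat * grid$n_lon)
      stop("values vector must have n_lat * n_lon entries", call. = FALSE)
    # row-major (lat outer) vector -> matrix with lat rows
    values <- matrix(values, nrow = grid$n_lat, ncol = grid$n_lon, byrow = TRUE)
  }
  storage.mode(values) <- "double"
  ok <- !is.na(values)
  if (any(!is.finite(values[ok])))
    stop("non-missing values must be finite", call. = FALSE)
  if (nonnegative && any(values[ok] < 0))
    stop("field values must be >= 0", call. = FALSE)
  structure(list(grid = grid, values = values, units = units),
            class = "gridded_field")
}

is_gridded_field <- function(x) inherits(x, "gridded_field")

#' @export
print.gridded_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("gridded_field [%s]: %d x %d, %d missing, range %.4g..%.4g\n",
              x$units, x$grid$n_lat, x$grid$n_lon, sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Row-major cell index
#'
#' Maps (latitude row, longitude column) to the flat zero-based cell index
#' used in the cell-to-country weight tables: `(lat_index - 1) * n_lon +
#' (lon_index - 1)` with 1-based matrix indices in, latitude outer.
#'
#' @param grid A `grid_spec`.
#' @param lat_index,lon_index 1-based row/column indices.
#' @return Zero-based integer cell index.
#' @export
cell_index <- function(grid, lat_index, lon_index) {
  stopifnot(all(lat_index >= 1 & lat_index <= grid$n_lat),
            all(lon_index >= 1 & lon_index <= grid$n_lon))
  (lat_index - 1L) * grid$n_lon + (lon_index - 1L)
}

# inverse of cell_index; returns list(lat, lon) of 1-based indices
cell_index_inv <- function(grid, index) {
  stopifnot(all(index >= 0 & index < grid$n_lat * grid$n_lon))
  list(lat = index %/% grid$n_lon + 1L, lon = index %% grid$n_lon + 1L)
}

# flatten a field matrix to the row-major (lat outer) vector ordering
field_vector <- function(field) as.vector(t(field$values))

#' Spherical cell areas
#'
#' Area of each spherical quadrilateral cell on a sphere of radius 6371 km:
#' `R^2 * dlon * (sin(lat_top) - sin(lat_bottom))`. Summed over the globe the
#' areas recover the full sphere surface `4 * pi * R^2` exactly (to floating
#' point), independent of resolution.
#'
#' @param grid A `grid_spec`.
#' @return A `gridded_field` of cell areas in km^2.
#' @export
cell_areas <- function(grid) {
  stopifnot(is_grid_spec(grid))
  edges <- -90 + grid$dlat * (0:grid$n_lat)
  band <- EARTH_RADIUS_KM^2 * (grid$dlon * pi / 180) *
    diff(sin(edges * pi / 180))
  gridded_field(grid, matrix(band, nrow = grid$n_lat, ncol = grid$n_lon),
                units = "km2")
}

#' Region assignment per grid cell
#'
#' Assigns each land cell to exactly one of six continental regions; ocean
#' cells carry `NA`. Used for regional burden aggregation.
#'
#' @param grid A `grid_spec`.
#' @param region Character matrix (`n_lat x n_lon`) with entries from
#'   [region_names()] or `NA` for ocean.
#' @return Object of class `region_map`.
#' @export
region_map <- function(grid, region) {
  stopifnot(is_grid_spec(grid), is.matrix(region),
            all(dim(region) == c(grid$n_lat, grid$n_lon)))
  known <- region[!is.na(region)]
  if (!all(known %in% region_names()))
    stop("unknown region label(s): ",
         paste(setdiff(unique(known), region_names()), collapse = ", "),
         call. = FALSE)
  structure(list(grid = grid, region = region), class = "region_map")
}

#' Continental region labels
#' @return Character vector of the six reporting regions.
#' @export
region_names <- function() {
  c("Africa", "North America", "Europe", "Asia", "South America", "Oceania")
}

#' @export
print.region_map <- function(x, ...) {
  tab <- table(factor(x$region, levels = region_names()))
  cat("region_map:", sum(!is.na(x$region)), "land cells\n")
  print(tab)
  invisible(x)
}

# ---- gridded field I/O (plain-text, self-describing) ------------------------

#' Write a gridded field (or monthly bundle) to a text file
#'
#' Plain-text serialisation: a `# key,value` header (grid dimensions, units,
#' number of time slices) followed by a CSV body with columns
#' `lat_index, lon_index[, month], value`. Missing cells are written as `NA`.
#' Values are written with full double precision (`%.17g`) so that
#' write-read-write is byte-stable.
#'
#' @param field A `gridded_field`, or a list of 12 `gridded_field`s for a
#'   monthly bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_field()], [roundtrip_field()]
#' @export
write_field <- function(field, path) {
  fields <- if (is_gridded_field(field)) list(field) else field
  stopifnot(length(fields) >= 1, all(vapply(fields, is_gridded_field, TRUE)))
  g <- fields[[1]]$grid
  for (f in fields) stop_if_grid_mismatch(g, f$grid, "bundle members")
  n_time <- length(fields)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# airburden gridded field v1",
    sprintf("# n_lat,%d", g$n_lat),
    sprintf("# n_lon,%d", g$n_lon),
    sprintf("# n_time,%d", n_time),
    sprintf("# units,%s", fields[[1]]$units),
    if (n_time == 1) "lat_index,lon_index,value"
    else "lat_index,lon_index,month,value"
  ), con)
  for (t in seq_len(n_time)) {
    v <- fields[[t]]$values
    idx <- cbind(rep(seq_len(g$n_lat), each = g$n_lon),
                 rep(seq_len(g$n_lon), times = g$n_lat))
    val <- ifelse(is.na(v[idx]), "NA", sprintf("%.17g", v[idx]))
    lines <- if (n_time == 1)
      sprintf("%d,%d,%s", idx[, 1], idx[, 2], val)
    else
      sprintf("%d,%d,%d,%s", idx[, 1], idx[, 2], t, val)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a gridded field written by [write_field()]
#'
#' @param path File path.
#' @param grid Optional expected `grid_spec`; a dimension mismatch between
#'   the file and `grid` is an error.
#' @param nonnegative Passed to [gridded_field()].
#' @return A `gridded_field`, or a list of `gridded_field`s if the file holds
#'   a monthly bundle.
#' @export
read_field <- function(path, grid = NULL, nonnegative = TRUE) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^# ", key, ","), hdr, value = TRUE)
    if (length(m) != 1)
      stop(sprintf("parse error in '%s': missing header variable '%s'",
                   path, key), call. = FALSE)
    sub(paste0("^# ", key, ","), "", m)
  }
  n_lat <- as.integer(get_hdr("n_lat"))
  n_lon <- as.integer(get_hdr("n_lon"))
  n_time <- as.integer(get_hdr("n_time"))
  units <- get_hdr("units")
  if (anyNA(c(n_lat, n_lon, n_time)))
    stop(sprintf("parse error in '%s': non-integer dimension header", path),
         call. = FALSE)
  if (!is.null(grid) && (grid$n_lat != n_lat || grid$n_lon != n_lon))
    stop(sprintf("dimension mismatch: file is %dx%d, expected %dx%d",
                 n_lat, n_lon, grid$n_lat, grid$n_lon), call. = FALSE)
  g <- if (is.null(grid)) make_grid(n_lat, n_lon) else grid
  body <- utils::read.csv(textConnection(lines[!startsWith(lines, "# ")]))
  need <- if (n_time == 1) c("lat_index", "lon_index", "value")
          else c("lat_index", "lon_index", "month", "value")
  if (!all(need %in% names(body)))
    stop(sprintf("parse error in '%s': missing column(s) %s", path,
                 paste(setdiff(need, names(body)), collapse = ", ")),
         call. = FALSE)
  one <- function(rows) {
    v <- matrix(NA_real_, n_lat, n_lon)
    v[cbind(rows$lat_index, rows$lon_index)] <- rows$value
    gridded_field(g, v, units = units, nonnegative = nonnegative)
  }
  if (n_time == 1) return(one(body))
  lapply(seq_len(n_time), function(t) one(body[body$month == t, , drop = FALSE]))
}

#' Write-then-read a field
#'
#' Serialises `field` to `path` and reads it back; the result equals the
#' input to full double precision with units and missing mask preserved.
#' Useful as an explicit persistence checkpoint between pipeline stages.
#'
#' @inheritParams write_field
#' @inheritParams read_field
#' @return The re-read `gridded_field` (or bundle).
#' @export
roundtrip_field <- function(field, path, nonnegative = TRUE) {
  write_field(field, path)
  g <- if (is_gridded_field(field)) field$grid else field[[1]]$grid
  read_field(path, grid = g, nonnegative = nonnegative)
}
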