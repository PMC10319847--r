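#' Gridded daily field
#'
#' Container for daily values of one variable on a regular latitude/longitude
#' grid, the common currency of the wind, temperature and precipitation
#' stages.  Time is indexed by a (year, season-day) pair so that the
#' June--August window arithmetic stays trivial; season day 1 is June 1 and a
#' non-leap 92-day season is assumed throughout.
#'
#' @param data numeric array with dimensions (time, lat, lon).
#' @param lat ascending latitudes in degrees north.
#' @param lon ascending longitudes in degrees east, in \[0, 360).
#' @param year integer year label of each time step.
#' @param sday integer day-of-season (1..season length) of each time step.
#' @param var variable name, e.g. `"v250"`, `"t2m"`, `"pr"`.
#' @param units units string, e.g. `"m s-1"`, `"K"`, `"mm day-1"`.
#'
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(data, lat, lon, year, sday, var, units) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (d[1] != length(year) || length(year) != length(sday))
    stop("time dimension of 'data' must match length of 'year' and 'sday'")
  if (d[2] != length(lat)) stop("lat dimension mismatch")
  if (d[3] != length(lon)) stop("lon dimension mismatch")
  if (is.unsorted(lat, strictly = TRUE)) stop("'lat' must be strictly ascending")
  if (is.unsorted(lon, strictly = TRUE)) stop("'lon' must be strictly ascending")
  if (any(lon < 0 | lon >= 360)) stop("'lon' must lie in [0, 360)")
  structure(
    list(data = data, lat = as.numeric(lat), lon = as.numeric(lon),
         year = as.integer(year), sday = as.integer(sday),
         var = as.character(var), units = as.character(units)),
    class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s]\n", x$var, x$units))
  cat(sprintf("  grid: %d lat (%.1f..%.1f) x %d lon (%.1f..%.1f)\n",
              length(x$lat), min(x$lat), max(x$lat),
              length(x$lon), min(x$lon), max(x$lon)))
  cat(sprintf("  time: %d days, years %d..%d, season days %d..%d\n",
              length(x$year), min(x$year), max(x$year),
              min(x$sday), max(x$sday)))
  invisible(x)
}

#' @export
dim.grid_field <- function(x) dim(x$data)

# Internal: view the time x lat x lon array as a (time x space) matrix,
# columns ordered lat-fastest (the native array unrolling).
field_matrix <- function(field) {
  d <- dim(field$data)
  matrix(field$data, nrow = d[1], ncol = d[2] * d[3])
}

# Internal: inverse of field_matrix().
matrix_to_field <- function(m, template, var = template$var,
                            units = template$units) {
  d <- dim(template$data)
  grid_field(array(m, dim = d), template$lat, template$lon,
             template$year, template$sday, var, units)
}

# Internal: cosine-latitude weights, normalised to sum to one.
coslat_weights <- function(lat) {
  w <- cos(lat * pi / 180)
  w / sum(w)
}
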