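#' Write a gridded daily field to CF-style NetCDF
#'
#' Dimensions lon/lat/time with degrees-east/north units; time is stored
#' as an index with the (year, season-day) labels as auxiliary integer
#' variables, so a write-read round trip is bit-exact.
#'
#' @param field a [grid_field()].
#' @param path output file path.
#' @param attrs optional named list of global attributes (e.g. the
#'   pipeline config hash).
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path, attrs = list()) {
  stopifnot(inherits(field, "grid_field"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dtime <- ncdf4::ncdim_def("time", "days", seq_along(field$year),
                            unlim = TRUE)
  vmain <- ncdf4::ncvar_def(field$var, field$units, list(dlon, dlat, dtime),
                            missval = NA_real_, prec = "double")
  vyear <- ncdf4::ncvar_def("year", "year", dtime, prec = "integer")
  vsday <- ncdf4::ncvar_def("season_day", "day", dtime, prec = "integer")
  nc <- ncdf4::nc_create(path, list(vmain, vyear, vsday))
  on.exit(ncdf4::nc_close(nc))
  # grid_field is (time, lat, lon); NetCDF wants (lon, lat, time)
  ncdf4::ncvar_put(nc, vmain, aperm(field$data, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, vyear, field$year)
  ncdf4::ncvar_put(nc, vsday, field$sday)
  for (a in names(attrs))
    ncdf4::ncatt_put(nc, 0, a, as.character(attrs[[a]]))
  invisible(path)
}

#' Read a gridded daily field from CF-style NetCDF
#'
#' Expects lon/lat/time dimensions, a units attribute on the variable,
#' and the year/season_day auxiliary variables written by
#' [write_gridded()] (absent those, time steps are labelled as consecutive
#' days of a single 92-day season per 92 steps).
#'
#' @param path NetCDF file path.
#' @param variable variable name to read.
#' @return A [grid_field()].
#' @export
read_gridded <- function(path, variable) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop(sprintf("variable '%s' not in %s (has: %s)", variable, path,
                 paste(names(nc$var), collapse = ", ")))
  units <- ncdf4::ncatt_get(nc, variable, "units")
  if (!units$hasatt)
    stop(sprintf("variable '%s' has no units attribute", variable))
  lon <- as.vector(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.vector(ncdf4::ncvar_get(nc, "lat"))
  if (is.unsorted(lon) || is.unsorted(lat))
    stop("non-monotonic coordinates")
  dat <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  nt <- dim(dat)[3]
  if ("year" %in% names(nc$var)) {
    year <- as.integer(ncdf4::ncvar_get(nc, "year"))
    sday <- as.integer(ncdf4::ncvar_get(nc, "season_day"))
  } else {
    year <- (seq_len(nt) - 1L) %/% 92L + 1L
    sday <- (seq_len(nt) - 1L) %% 92L + 1L
  }
  grid_field(aperm(dat, c(3, 2, 1)), lat, lon, year, sday,
             variable, units$value)
}

#' Conservative block-mean regridding to a coarser resolution
#'
#' Aggregates fine cells onto a coarser regular grid by cosine-latitude-
#' weighted averaging of the fine cells whose centers fall in each coarse
#' cell (the usual first-order conservative regridding for fields given
#' at cell centers, e.g. 0.25-degree reanalysis onto the 1-degree analysis
#' grid).
#'
#' @param field a [grid_field()].
#' @param step target grid spacing in degrees (a multiple of the input
#'   spacing).
#' @return A [grid_field()] on the coarser grid; coarse cell centers are
#'   the weighted means of their member fine-cell coordinates.
#' @export
regrid_field <- function(field, step) {
  lat_bins <- floor((field$lat - min(field$lat)) / step)
  lon_bins <- floor((field$lon - min(field$lon)) / step)
  new_lat <- as.vector(tapply(field$lat, lat_bins, mean))
  new_lon <- as.vector(tapply(field$lon, lon_bins, mean))
  w <- cos(field$lat * pi / 180)
  nt <- dim(field$data)[1]
  out <- array(0, c(nt, length(new_lat), length(new_lon)))
  for (i in seq_along(new_lat)) {
    li <- which(lat_bins == i - 1L)
    wi <- w[li] / sum(w[li])
    sub <- array(0, c(nt, length(field$lon)))
    for (j in seq_along(li))
      sub <- sub + wi[j] * field$data[, li[j], ]
    for (k in seq_along(new_lon)) {
      lj <- which(lon_bins == k - 1L)
      out[, i, k] <- rowMeans(sub[, lj, drop = FALSE])
    }
  }
  grid_field(out, new_lat, new_lon, field$year, field$sday,
             field$var, field$units)
}

#' Write detected events to CSV
#'
#' @param events a `wave_events` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("year", "week", "wavenumber",
                                             "amplitude", "center_sday",
                                             "center_date")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read events from CSV written by [write_events_csv()]
#'
#' @param path CSV path.
#' @return A `wave_events` data frame.
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path)
  ev$center_date <- as.Date(ev$center_date)
  class(ev) <- c("wave_events", "data.frame")
  ev
}

# Internal: FNV-1a hash of a string, as 8 hex digits; used to stamp
# pipeline outputs with their configuration.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Internal: canonical JSON of a config (drops non-scalars it cannot
# represent losslessly in a stable way).
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  fnv1a(as.character(js))
}
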