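#' Configuration for the synthetic reanalysis/yield generator
#'
#' Bundles every knob of the synthetic-data module: the grid and season
#' geometry, the planted wavenumbers with their background amplitude
#' climatology and event rate, the surface coupling strengths, and the
#' regional yield model (technology trend, event-year yield loss, pairwise
#' shock concurrence, noise).  A single integer `seed` makes every generated
#' artifact bit-reproducible.
#'
#' Defaults mirror the study conditions of the observational analysis the
#' generator emulates: a 55-summer record, a 1-degree grid spanning
#' 25--75N, zonal wavenumbers 5 and 7 with roughly one exceedance week per
#' season each, and five breadbasket-like regions.
#'
#' @param years number of seasons (>= 10).
#' @param season_days days per season; 92 labels June 1--August 31 on a
#'   non-leap calendar.
#' @param lat_range,lon_range grid extents in degrees; the wind grid must
#'   span the 37.5--57.5N analysis band.
#' @param grid_step grid spacing in degrees (same for lat and lon).
#' @param wavenumbers integer zonal wavenumbers with planted events.
#' @param base_amplitude_mean,base_amplitude_sd background weekly wave
#'   amplitude climatology, m/s, recycled across wavenumbers.
#' @param event_rate expected exceedance weeks per season per wavenumber.
#' @param event_amplitude amplitude (m/s) assigned to planted event weeks;
#'   default `base_amplitude_mean + 3*base_amplitude_sd + 1` keeps planted
#'   weeks separable from the background even when `base_amplitude_sd = 0`.
#' @param planted_weeks optional data.frame (year, week, wavenumber) that
#'   overrides the Bernoulli event draw with an explicit plant.
#' @param coupling_temp surface warming per m/s of ridge amplitude (K per
#'   m/s); ridges sit a quarter wavelength downstream of the southerly
#'   maximum of the meridional wind.
#' @param coupling_precip fractional precipitation suppression per m/s of
#'   ridge amplitude.
#' @param temp_base,precip_base background 2 m temperature (K) and
#'   precipitation (mm/day).
#' @param temp_trend linear warming over the record, K per season index.
#' @param regions character vector of region names (>= 2).
#' @param yield_trend length-2 numeric c(intercept, slope) of the linear
#'   technology trend in t/ha (slope per year), shared across regions, or a
#'   list of such vectors, one per region.
#' @param event_effect fractional yield loss in multi-event years, in \[0, 1).
#' @param concurrence correlation of cross-region yield shocks in
#'   multi-event years (shocks are independent otherwise).
#' @param driver_wavenumber the wavenumber whose multi-event years carry the
#'   yield effect; default the first of `wavenumbers`.
#' @param area_ha harvested area per region (ha), recycled.
#' @param noise_sd named list of noise levels: `wind`, `temp`, `precip`
#'   (daily additive SD in field units) and `yield` (SD of the lognormal
#'   yield shock).
#' @param seed integer seed; required, every generator call derives its
#'   stream from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(years = 55,
                       season_days = 92,
                       lat_range = c(25, 75),
                       lon_range = c(0, 360),
                       grid_step = 1,
                       wavenumbers = c(5L, 7L),
                       base_amplitude_mean = 2.0,
                       base_amplitude_sd = 0.8,
                       event_rate = 1.0,
                       event_amplitude = NULL,
                       planted_weeks = NULL,
                       coupling_temp = 1.0,
                       coupling_precip = 0.05,
                       temp_base = 288,
                       precip_base = 2.5,
                       temp_trend = 0,
                       regions = c("NAM", "WEU", "EEU", "IND", "EAS"),
                       yield_trend = c(3, 0.03),
                       event_effect = 0.05,
                       concurrence = 0.3,
                       driver_wavenumber = NULL,
                       area_ha = 1e6,
                       noise_sd = list(),
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config: an explicit integer 'seed' is required")
  seed <- as.integer(seed)
  years <- as.integer(years)
  if (years < 10L) stop("sim_config: 'years' must be >= 10")
  if (event_rate < 0) stop("sim_config: 'event_rate' must be >= 0")
  if (event_effect < 0 || event_effect >= 1)
    stop("sim_config: 'event_effect' must lie in [0, 1)")
  if (length(regions) < 2L) stop("sim_config: at least 2 regions required")
  if (abs(concurrence) > 1) stop("sim_config: 'concurrence' must be in [-1, 1]")
  wavenumbers <- as.integer(wavenumbers)
  nk <- length(wavenumbers)
  base_amplitude_mean <- rep_len(base_amplitude_mean, nk)
  base_amplitude_sd <- rep_len(base_amplitude_sd, nk)
  if (any(base_amplitude_sd < 0)) stop("sim_config: amplitude SD must be >= 0")
  if (is.null(event_amplitude))
    event_amplitude <- base_amplitude_mean + 3 * base_amplitude_sd + 1
  event_amplitude <- rep_len(event_amplitude, nk)
  if (is.null(driver_wavenumber)) driver_wavenumber <- wavenumbers[1]
  driver_wavenumber <- as.integer(driver_wavenumber)
  if (!driver_wavenumber %in% wavenumbers)
    stop("sim_config: 'driver_wavenumber' must be one of 'wavenumbers'")
  ns <- list(wind = 0.5, temp = 0.5, precip = 0.5, yield = 0.05)
  ns[names(noise_sd)] <- noise_sd
  if (any(unlist(ns) < 0)) stop("sim_config: noise SDs must be >= 0")
  if (!is.list(yield_trend)) yield_trend <- rep(list(yield_trend), length(regions))
  if (length(yield_trend) != length(regions))
    stop("sim_config: one 'yield_trend' per region required")
  if (!is.null(planted_weeks)) {
    stopifnot(is.data.frame(planted_weeks),
              all(c("year", "week", "wavenumber") %in% names(planted_weeks)))
  }
  lat <- seq(lat_range[1], lat_range[2], by = grid_step)
  lon <- seq(lon_range[1], lon_range[2] - grid_step, by = grid_step)
  structure(
    list(years = years, season_days = as.integer(season_days),
         lat = lat, lon = lon, grid_step = grid_step,
         wavenumbers = wavenumbers,
         base_amplitude_mean = base_amplitude_mean,
         base_amplitude_sd = base_amplitude_sd,
         event_rate = event_rate, event_amplitude = event_amplitude,
         planted_weeks = planted_weeks,
         coupling_temp = coupling_temp, coupling_precip = coupling_precip,
         temp_base = temp_base, precip_base = precip_base,
         temp_trend = temp_trend,
         regions = regions, yield_trend = yield_trend,
         event_effect = event_effect, concurrence = concurrence,
         driver_wavenumber = driver_wavenumber,
         area_ha = rep_len(area_ha, length(regions)),
         noise_sd = ns, seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d seasons x %d days, grid %.3g deg (%g..%gN, %g..%gE)\n",
              x$years, x$season_days, x$grid_step,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  wavenumbers k = %s, event rate %.2f/season, seed %d\n",
              paste(x$wavenumbers, collapse = ", "), x$event_rate, x$seed))
  cat(sprintf("  %d regions, event effect %.1f%%, concurrence %.2f\n",
              length(x$regions), 100 * x$event_effect, x$concurrence))
  invisible(x)
}

# Internal: number of whole analysis weeks per season (92 days -> 13; the
# leftover day 92 is never part of a week).
n_weeks <- function(config) config$season_days %/% 7L
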