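# Shared fixtures, all built in code at test time.

# A small grid_field from a function f(t, lat, lon) (vectorised or not).
make_field <- function(f, years = 3, season_days = 92,
                       lat = seq(30, 65, by = 5), lon = seq(0, 350, by = 10),
                       var = "t2m", units = "K") {
  nt <- years * season_days
  year <- rep(seq_len(years), each = season_days)
  sday <- rep(seq_len(season_days), years)
  dat <- array(0, c(nt, length(lat), length(lon)))
  for (i in seq_along(lat))
    for (j in seq_along(lon))
      dat[, i, j] <- f(seq_len(nt), lat[i], lon[j])
  grid_field(dat, lat, lon, year, sday, var, units)
}

# A wave_events table from bare (year, week) pairs.
make_events <- function(year, week, wavenumber = 5L) {
  ev <- data.frame(year = year, week = week,
                   wavenumber = rep(wavenumber, length(year)),
                   amplitude = rep(10, length(year)),
                   center_sday = (week - 1L) * 7L + 4L)
  ev$center_date <- as.Date(sprintf("%04d-06-01", ev$year)) + ev$center_sday - 1
  class(ev) <- c("wave_events", "data.frame")
  ev
}

# An event_calendar with the given multi-event and zero-event years;
# remaining years in 1..n_years are single-event.
make_calendar <- function(multi_years, zero_years, n_years,
                          wavenumber = 5L) {
  yrs <- seq_len(n_years)
  single <- setdiff(yrs, c(multi_years, zero_years))
  ev <- rbind(
    if (length(multi_years))
      data.frame(year = rep(multi_years, each = 2),
                 week = rep(c(2L, 8L), length(multi_years))),
    if (length(single))
      data.frame(year = single, week = 5L))
  if (is.null(ev)) ev <- data.frame(year = integer(), week = integer())
  event_calendar(make_events(ev$year, ev$week, wavenumber),
                 c(1, n_years), wavenumber)
}

# A yield table for one region with the given yearly yields.
make_yields <- function(yield, region = "R1", years = seq_along(yield)) {
  data.frame(region = region, year = years,
             production = yield * 1e6, area = 1e6, yield = yield)
}

# Quiet config for fast simulations.
fast_config <- function(...) {
  sim_config(grid_step = 5, ...)
}
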