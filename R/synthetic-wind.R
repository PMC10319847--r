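#' Generate weekly wave amplitudes, phases and the planted event truth
#'
#' The amplitude-level core of the synthetic wind generator.  For every
#' season week and configured wavenumber it draws a background weekly
#' amplitude from the truncated-normal base climatology, overrides planted
#' event weeks with `event_amplitude`, and draws a phase that is held fixed
#' within the week (quasi-stationarity).  The ground truth records, per
#' wavenumber, exactly those weeks whose generated amplitude exceeds the
#' empirical JJA climatology mean by more than 1.5 sample standard
#' deviations -- the same rule the downstream detector applies -- so that on
#' noise-free fields detected and true events coincide by construction.
#'
#' @param config a [sim_config()].
#' @return A list with `spectrum` (a `wave_spectrum` data frame of the true
#'   weekly amplitudes/phases) and `truth` (amplitude/phase/planted arrays,
#'   the implied event table, and the empirical amplitude climatology).
#' @export
gen_wave_spectrum <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nw <- n_weeks(config)
  ny <- config$years
  nk <- length(config$wavenumbers)
  dimw <- c(ny, nw, nk)
  p_week <- min(1, config$event_rate / nw)
  planted <- array(stats::runif(prod(dimw)) < p_week, dim = dimw)
  amp <- array(pmax(0, stats::rnorm(prod(dimw),
                                    mean = rep(config$base_amplitude_mean, each = ny * nw),
                                    sd = rep(config$base_amplitude_sd, each = ny * nw))),
               dim = dimw)
  if (!is.null(config$planted_weeks)) {
    planted[] <- FALSE
    pw <- config$planted_weeks
    ik <- match(pw$wavenumber, config$wavenumbers)
    if (anyNA(ik)) stop("planted_weeks refers to unconfigured wavenumbers")
    planted[cbind(pw$year, pw$week, ik)] <- TRUE
  }
  for (i in seq_len(nk))
    amp[, , i][planted[, , i]] <- config$event_amplitude[i]
  phase <- array(stats::runif(prod(dimw), 0, 2 * pi), dim = dimw)

  # ground-truth events: the 1.5-SD exceedance rule applied to the true
  # weekly amplitudes, with the empirical (sample-SD) climatology
  clim <- data.frame(
    wavenumber = config$wavenumbers,
    mean = apply(amp, 3, mean),
    sd = apply(amp, 3, stats::sd))
  ev <- do.call(rbind, lapply(seq_len(nk), function(i) {
    hit <- which(amp[, , i] > clim$mean[i] + 1.5 * clim$sd[i], arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(year = hit[, 1], week = hit[, 2],
               wavenumber = config$wavenumbers[i],
               amplitude = amp[, , i][hit])
  }))
  if (is.null(ev))
    ev <- data.frame(year = integer(), week = integer(),
                     wavenumber = integer(), amplitude = numeric())
  ev <- ev[order(ev$wavenumber, ev$year, ev$week), , drop = FALSE]
  rownames(ev) <- NULL

  grid <- expand.grid(week = seq_len(nw), year = seq_len(ny))
  spectrum <- do.call(rbind, lapply(seq_len(nk), function(i) {
    data.frame(year = grid$year, week = grid$week,
               wavenumber = config$wavenumbers[i],
               amplitude = as.vector(t(amp[, , i])),
               phase = as.vector(t(phase[, , i])))
  }))
  class(spectrum) <- c("wave_spectrum", "data.frame")
  truth <- structure(
    list(amplitude = amp, phase = phase, planted = planted,
         events = ev, climatology = clim, config = config),
    class = "wave_truth")
  list(spectrum = spectrum, truth = truth)
}

#' Generate a daily meridional wind field with planted wave events
#'
#' Builds a reanalysis-like daily 250 mb meridional wind field on the
#' configured grid.  Within each week the zonal profile is a superposition
#' of standing waves `A_k cos(k*lon - phi_k)` with the weekly amplitudes and
#' phases from [gen_wave_spectrum()]; the profile is uniform across latitude
#' (the meridional mean then returns it unchanged) and daily white noise is
#' added on top.  Day 92, which belongs to no analysis week, reuses the
#' week-13 wave state.
#'
#' @param config a [sim_config()] whose grid spans the 37.5--57.5N band.
#' @return An object of class `wind_sim`: list with `field` (a
#'   [grid_field()] of daily wind, m/s) and `truth` (see
#'   [gen_wave_spectrum()]).
#' @export
gen_wind_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (min(config$lat) > 37.5 || max(config$lat) < 57.5)
    stop(sprintf(
      "grid (%g..%gN) must span the 37.5-57.5N analysis band",
      min(config$lat), max(config$lat)))
  gs <- gen_wave_spectrum(config)
  truth <- gs$truth
  nw <- n_weeks(config)
  ny <- config$years
  nk <- length(config$wavenumbers)
  lam <- config$lon * pi / 180
  nlon <- length(lam)
  nlat <- length(config$lat)

  # weekly zonal profiles, rows ordered (week fastest within year)
  W <- matrix(0, ny * nw, nlon)
  for (i in seq_len(nk)) {
    k <- config$wavenumbers[i]
    A <- as.vector(t(truth$amplitude[, , i]))
    ph <- as.vector(t(truth$phase[, , i]))
    W <- W + (A * cos(ph)) %*% t(cos(k * lam)) +
             (A * sin(ph)) %*% t(sin(k * lam))
  }

  sday <- rep(seq_len(config$season_days), ny)
  year <- rep(seq_len(ny), each = config$season_days)
  week_of_day <- pmin((sday - 1L) %/% 7L + 1L, nw)
  widx <- (year - 1L) * nw + week_of_day
  V <- W[widx, , drop = FALSE]                     # daily profiles [T, nlon]
  dat <- aperm(array(V, dim = c(length(sday), nlon, nlat)), c(1, 3, 2))
  if (config$noise_sd$wind > 0)
    dat <- dat + stats::rnorm(length(dat), sd = config$noise_sd$wind)
  field <- grid_field(dat, config$lat, config$lon, year, sday,
                      var = "v250", units = "m s-1")
  structure(list(field = field, truth = truth), class = "wind_sim")
}

# Internal: weekly ridge pattern (quarter wavelength downstream of the
# southerly wind maximum), rows ordered like the weekly profile matrix.
ridge_pattern_matrix <- function(truth) {
  config <- truth$config
  lam <- config$lon * pi / 180
  ny <- dim(truth$amplitude)[1]
  nw <- dim(truth$amplitude)[2]
  P <- matrix(0, ny * nw, length(lam))
  for (i in seq_along(config$wavenumbers)) {
    k <- config$wavenumbers[i]
    A <- as.vector(t(truth$amplitude[, , i]))
    ph <- as.vector(t(truth$phase[, , i]))
    # A sin(k lam - phi) = A cos(k lam - phi - pi/2)
    P <- P + (A * sin(-ph)) %*% t(cos(k * lam)) +
             (A * cos(ph)) %*% t(sin(k * lam))
  }
  P
}

#' Generate surface temperature and precipitation coupled to the wave field
#'
#' Temperature anomalies are phase-locked to the wave: warm under ridges
#' (a quarter wavelength downstream of the southerly meridional-wind
#' maximum), with strength `coupling_temp` Kelvin per m/s of wave
#' amplitude, on top of a smooth within-season cycle, an optional linear
#' trend across the record, and daily white noise.  Precipitation is
#' anti-correlated with the ridge pattern (`coupling_precip` fractional
#' suppression per m/s) around `precip_base` and clipped at zero, so the
#' generated field is non-negative for every seed.
#'
#' @param config the [sim_config()] used for the wind.
#' @param wind the `wind_sim` returned by [gen_wind_field()].
#' @return list with `temp` and `precip` [grid_field()]s (K, mm/day) and
#'   `truth` carrying the planted ridge patterns.
#' @export
gen_surface_fields <- function(config, wind) {
  stopifnot(inherits(config, "sim_config"), inherits(wind, "wind_sim"))
  set.seed(config$seed + 1L)
  truth <- wind$truth
  nw <- n_weeks(config)
  P <- ridge_pattern_matrix(truth)
  nlon <- length(config$lon)
  nlat <- length(config$lat)
  sday <- wind$field$sday
  year <- wind$field$year
  nT <- length(sday)
  week_of_day <- pmin((sday - 1L) %/% 7L + 1L, nw)
  widx <- (year - 1L) * nw + week_of_day
  Pd <- P[widx, , drop = FALSE]

  cyc <- 2 * sin(pi * (sday - 1) / (config$season_days - 1))   # seasonal cycle, K
  tgrow <- config$temp_trend * (year - 1)
  Tm <- config$temp_base + cyc + tgrow + config$coupling_temp * Pd
  tdat <- aperm(array(Tm, dim = c(nT, nlon, nlat)), c(1, 3, 2))
  if (config$noise_sd$temp > 0)
    tdat <- tdat + stats::rnorm(length(tdat), sd = config$noise_sd$temp)
  temp <- grid_field(tdat, config$lat, config$lon, year, sday,
                     var = "t2m", units = "K")

  Pm <- config$precip_base * (1 - config$coupling_precip * Pd)
  pdat <- aperm(array(Pm, dim = c(nT, nlon, nlat)), c(1, 3, 2))
  if (config$noise_sd$precip > 0)
    pdat <- pdat + stats::rnorm(length(pdat), sd = config$noise_sd$precip)
  pdat <- pmax(pdat, 0)
  precip <- grid_field(pdat, config$lat, config$lon, year, sday,
                       var = "pr", units = "mm day-1")

  truth$ridge_pattern <- P
  list(temp = temp, precip = precip, truth = truth)
}
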