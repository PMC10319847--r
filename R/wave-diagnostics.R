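#' Cosine-latitude-weighted meridional mean of a daily field
#'
#' Collapses the latitude dimension over a mid-latitude band (default
#' 37.5--57.5N, the band used for the 250 mb wave analysis) with
#' cosine-latitude area weights, producing one zonal profile per day.
#'
#' @param field a [grid_field()] covering the band.
#' @param band length-2 latitude interval in degrees north.
#' @return An object of class `zonal_profiles`: list with `values`
#'   (days x longitudes matrix), `lon`, `year`, `sday`.
#' @export
meridional_mean <- function(field, band = c(37.5, 57.5)) {
  stopifnot(inherits(field, "grid_field"), length(band) == 2)
  band <- sort(band)
  if (band[1] < min(field$lat) || band[2] > max(field$lat))
    stop(sprintf(
      "latitude band %g-%gN outside grid coverage %g-%gN; missing latitudes %s",
      band[1], band[2], min(field$lat), max(field$lat),
      paste(c(if (band[1] < min(field$lat))
                sprintf("%g-%g", band[1], min(field$lat)),
              if (band[2] > max(field$lat))
                sprintf("%g-%g", max(field$lat), band[2])), collapse = ", ")))
  idx <- which(field$lat >= band[1] & field$lat <= band[2])
  if (!length(idx)) stop("no grid latitudes inside the requested band")
  w <- coslat_weights(field$lat[idx])
  out <- matrix(0, dim(field$data)[1], length(field$lon))
  for (j in seq_along(idx))
    out <- out + w[j] * field$data[, idx[j], ]
  structure(list(values = out, lon = field$lon,
                 year = field$year, sday = field$sday),
            class = "zonal_profiles")
}

#' Weekly averages of daily zonal profiles
#'
#' Partitions each 92-day season into 13 consecutive non-overlapping 7-day
#' blocks (days 1--91; the leftover day 92 is dropped) and averages the
#' daily profiles within each block.  The weekly mean acts as a low-pass
#' anti-aliasing filter on the sub-weekly variability.  Each week carries
#' its center day (day 4 of the block) for the event-centered surface
#' anomaly windows.
#'
#' @param profiles a `zonal_profiles` object from [meridional_mean()].
#' @return An object of class `zonal_weekly`: list with `values` (weeks x
#'   longitudes), `lon`, `year`, `week`, `center_sday`.
#' @export
weekly_average <- function(profiles) {
  stopifnot(inherits(profiles, "zonal_profiles"))
  sdays <- profiles$sday
  years <- sort(unique(profiles$year))
  nsd <- max(sdays)
  for (y in years) {
    missing <- setdiff(seq_len(nsd), sdays[profiles$year == y])
    if (length(missing))
      stop(sprintf("year %d is missing season days: %s", y,
                   paste(missing, collapse = ", ")))
  }
  nwk <- nsd %/% 7L
  keep <- sdays <= nwk * 7L
  wk <- (sdays[keep] - 1L) %/% 7L + 1L
  key <- sprintf("%06d-%02d", profiles$year[keep], wk)
  V <- rowsum(profiles$values[keep, , drop = FALSE], key, reorder = TRUE) / 7
  yw <- expand.grid(week = seq_len(nwk), year = years)
  yw <- yw[order(yw$year, yw$week), ]
  structure(list(values = V, lon = profiles$lon,
                 year = yw$year, week = yw$week,
                 center_sday = (yw$week - 1L) * 7L + 4L),
            class = "zonal_weekly")
}

#' Zonal-wavenumber decomposition of weekly wind profiles
#'
#' Fast Fourier decomposition of each weekly zonal profile into standing
#' waves.  The amplitude convention is chosen so that a profile
#' `A*cos(k*lon - phi)` yields amplitude exactly `A` at wavenumber `k`
#' (and `phi` is recovered modulo 2*pi); at the Nyquist wavenumber
#' `n_lon/2` the amplitude is the coefficient of the `(-1)^j` mode.
#'
#' @param weekly a `zonal_weekly` object.
#' @param k_max largest wavenumber returned (default 10; must be <=
#'   `n_lon/2`).
#' @return A `wave_spectrum` data frame with columns year, week,
#'   wavenumber, amplitude, phase, plus attributes `profile_mean` and
#'   `profile_msq` (per-profile mean and mean square, for energy checks).
#' @export
fourier_decompose <- function(weekly, k_max = 10L) {
  stopifnot(inherits(weekly, "zonal_weekly"))
  lon <- weekly$lon
  n <- length(lon)
  step <- diff(lon)
  if (max(abs(step - step[1])) > 1e-8)
    stop("longitude grid must be uniform")
  if (abs(n * step[1] - 360) > 1e-6)
    stop("longitude grid must be periodic over 360 degrees")
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > n %/% 2L)
    stop("k_max must lie in [1, n_lon/2]")
  V <- weekly$values
  np <- nrow(V)
  F <- stats::mvfft(t(V)) / n                      # [n, np]
  lam0 <- lon[1] * pi / 180
  out <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    ck <- F[k + 1L, ]
    amp <- if (2L * k == n) Mod(ck) else 2 * Mod(ck)
    ph <- (k * lam0 - Arg(ck)) %% (2 * pi)
    out[[k]] <- data.frame(year = weekly$year, week = weekly$week,
                           wavenumber = k, amplitude = amp, phase = ph)
  }
  spec <- do.call(rbind, out)
  spec <- spec[order(spec$year, spec$week, spec$wavenumber), ]
  rownames(spec) <- NULL
  attr(spec, "profile_mean") <- Re(F[1L, ])
  attr(spec, "profile_msq") <- rowMeans(V^2)
  class(spec) <- c("wave_spectrum", "data.frame")
  spec
}

#' JJA amplitude climatology per wavenumber
#'
#' Mean and standard deviation of the weekly amplitudes over all season
#' weeks of a reference period, the baseline against which high-amplitude
#' events are defined.
#'
#' @param spectra a `wave_spectrum` data frame.
#' @param period optional year range (length-2) restricting the reference
#'   period; default all years present.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A `wave_climatology` data frame: wavenumber, mean, sd, n_weeks,
#'   with the reference years as an attribute.
#' @export
build_climatology <- function(spectra, period = NULL,
                              sd_type = c("sample", "population")) {
  stopifnot(inherits(spectra, "data.frame"),
            all(c("year", "wavenumber", "amplitude") %in% names(spectra)))
  sd_type <- match.arg(sd_type)
  if (!is.null(period))
    spectra <- spectra[spectra$year >= period[1] & spectra$year <= period[2], ]
  if (!nrow(spectra)) stop("no spectra in the reference period")
  if (length(unique(spectra$year)) < 2L)
    stop("climatology requires at least 2 seasons")
  sp <- split(spectra$amplitude, spectra$wavenumber)
  out <- data.frame(
    wavenumber = as.integer(names(sp)),
    mean = vapply(sp, mean, 0.0),
    sd = vapply(sp, function(a) {
      s <- stats::sd(a)
      if (sd_type == "population") s * sqrt((length(a) - 1) / length(a)) else s
    }, 0.0),
    n_weeks = vapply(sp, length, 0L))
  rownames(out) <- NULL
  attr(out, "years") <- range(spectra$year)
  class(out) <- c("wave_climatology", "data.frame")
  out
}

#' Detect high-amplitude wave events
#'
#' A wave event is a season week whose amplitude at a given wavenumber
#' strictly exceeds the climatological mean by more than `threshold_sd`
#' standard deviations.  Each event carries its amplitude and center day
#' (day 4 of the 7-day block) for the event-centered surface windows.
#'
#' @param spectra a `wave_spectrum` data frame.
#' @param climatology a `wave_climatology` covering the queried wavenumbers.
#' @param threshold_sd exceedance threshold in climatological SD units
#'   (default 1.5).
#' @param wavenumbers wavenumbers to scan; default those in `climatology`.
#' @return A `wave_events` data frame: year, week, wavenumber, amplitude,
#'   center_sday, center_date (calendar date with season day 1 = June 1).
#' @export
detect_events <- function(spectra, climatology, threshold_sd = 1.5,
                          wavenumbers = NULL) {
  stopifnot(inherits(climatology, "data.frame"))
  if (is.null(wavenumbers)) wavenumbers <- climatology$wavenumber
  missing_k <- setdiff(wavenumbers, climatology$wavenumber)
  if (length(missing_k))
    stop("climatology does not cover wavenumber(s) ",
         paste(missing_k, collapse = ", "))
  out <- lapply(wavenumbers, function(k) {
    cl <- climatology[climatology$wavenumber == k, ]
    sk <- spectra[spectra$wavenumber == k, ]
    # strict exceedance; the tolerance keeps float jitter on numerically
    # constant amplitude records from registering as ties broken upward
    tol <- 1e-8 * (abs(cl$mean) + cl$sd)
    hit <- sk$amplitude - (cl$mean + threshold_sd * cl$sd) > tol
    sk[hit, c("year", "week", "wavenumber", "amplitude")]
  })
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$wavenumber, ev$year, ev$week), , drop = FALSE]
  rownames(ev) <- NULL
  ev$center_sday <- (ev$week - 1L) * 7L + 4L
  ev$center_date <- as.Date(sprintf("%04d-06-01", ev$year)) + ev$center_sday - 1L
  class(ev) <- c("wave_events", "data.frame")
  ev
}

#' @export
print.wave_events <- function(x, ...) {
  cat(sprintf("<wave_events> %d events, wavenumbers %s, years %s\n",
              nrow(x), paste(sort(unique(x$wavenumber)), collapse = ", "),
              if (nrow(x)) paste(range(x$year), collapse = "..") else "-"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Per-year event counts and year classes
#'
#' Tabulates events per (year, wavenumber) and classifies each summer as
#' `"multi"` (at least `multi_min` events, default 2), `"zero"` (none) or
#' `"single"` (in between; excluded from composites and from both LMF
#' conditioning sets).
#'
#' @param events a `wave_events` data frame.
#' @param years the full year range analysed (vector of years or length-2
#'   range); years without events must be representable.
#' @param wavenumbers wavenumbers to tabulate; default those in `events`.
#' @param multi_min minimum event count for the multi-event class.
#' @return An `event_calendar` data frame: year, wavenumber, n_events,
#'   class.
#' @export
event_calendar <- function(events, years, wavenumbers = NULL,
                           multi_min = 2L) {
  if (length(years) == 2L) years <- seq(years[1], years[2])
  if (is.null(wavenumbers)) wavenumbers <- sort(unique(events$wavenumber))
  if (!length(wavenumbers)) stop("no wavenumbers to tabulate")
  out <- do.call(rbind, lapply(wavenumbers, function(k) {
    ek <- events[events$wavenumber == k, ]
    n <- vapply(years, function(y) sum(ek$year == y), 0L)
    data.frame(year = years, wavenumber = k, n_events = n)
  }))
  out$class <- ifelse(out$n_events >= multi_min, "multi",
                      ifelse(out$n_events == 0L, "zero", "single"))
  attr(out, "multi_min") <- multi_min
  class(out) <- c("event_calendar", "data.frame")
  out
}

#' Years in a given calendar class
#'
#' @param calendar an [event_calendar()].
#' @param wavenumber the wavenumber of interest.
#' @param class `"multi"`, `"zero"` or `"single"`.
#' @return Integer vector of years.
#' @export
calendar_years <- function(calendar, wavenumber,
                           class = c("multi", "zero", "single")) {
  class <- match.arg(class)
  sel <- calendar$wavenumber == wavenumber & calendar$class == class
  calendar$year[sel]
}

#' @export
summary.event_calendar <- function(object, ...) {
  tab <- do.call(rbind, lapply(split(object, object$wavenumber), function(d) {
    data.frame(wavenumber = d$wavenumber[1],
               n_events = sum(d$n_events),
               multi_years = sum(d$class == "multi"),
               single_years = sum(d$class == "single"),
               zero_years = sum(d$class == "zero"))
  }))
  rownames(tab) <- NULL
  tab
}
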