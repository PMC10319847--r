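#' Detrend a gridded daily field and remove the seasonal cycle
#'
#' Per grid point, an ordinary-least-squares linear trend in time is
#' subtracted over the analysis period, followed by subtraction of the
#' day-in-season climatological mean (computed on the detrended data), so
#' anomalies have exactly zero day-of-season mean over the reference
#' period at every grid point.
#'
#' @param field a [grid_field()] with at least 2 years of data.
#' @param period optional length-2 year range restricting the data used.
#' @return A [grid_field()] of anomalies with attributes `trend_slope`
#'   (lat x lon, units per year) and `period`.
#' @export
detrend_field <- function(field, period = NULL) {
  stopifnot(inherits(field, "grid_field"))
  if (!is.null(period)) {
    if (period[1] < min(field$year) || period[2] > max(field$year))
      stop("requested period outside the data range")
    keep <- field$year >= period[1] & field$year <= period[2]
    field <- grid_field(field$data[keep, , , drop = FALSE], field$lat,
                        field$lon, field$year[keep], field$sday[keep],
                        field$var, field$units)
  }
  if (length(unique(field$year)) < 2L)
    stop("detrending requires at least 2 years of data")
  M <- field_matrix(field)
  # linear trend against the (centered) year index: orthogonal to the
  # seasonal cycle, so a pure repeating cycle contributes no spurious slope
  tc <- field$year - mean(field$year)
  beta <- as.vector(crossprod(tc, M)) / sum(tc^2)
  M <- M - outer(tc, beta)
  clim <- rowsum(M, field$sday, reorder = TRUE)
  clim <- clim / as.vector(table(field$sday))
  M <- M - clim[match(field$sday, sort(unique(field$sday))), , drop = FALSE]
  out <- matrix_to_field(M, field)
  attr(out, "trend_slope") <- matrix(beta, length(field$lat), length(field$lon))
  attr(out, "period") <- range(field$year)
  out
}

#' Event-centered weekly anomaly map
#'
#' Extracts the 7-day window centered on a given day of a given season and
#' collapses it to one map: the mean of the daily anomalies for
#' temperature and wind, the 7-day aggregate (sum) for precipitation.
#' Windows truncated by the season edge shrink to the available days and
#' the result is flagged via the `"truncated"` attribute.
#'
#' @param anoms an anomaly [grid_field()] (see [detrend_field()]).
#' @param year season of the event.
#' @param center_sday center day of the window (day-of-season).
#' @param mode `"mean"` or `"sum"`.
#' @return lat x lon matrix with attributes `n_days` and `truncated`.
#' @export
weekly_anomaly <- function(anoms, year, center_sday,
                           mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(anoms, "grid_field"))
  win <- (center_sday - 3L):(center_sday + 3L)
  rows <- which(anoms$year == year & anoms$sday %in% win)
  if (!length(rows))
    stop(sprintf("no data in year %d around season day %d", year, center_sday))
  sub <- anoms$data[rows, , , drop = FALSE]
  out <- apply(sub, c(2, 3), if (mode == "mean") mean else sum)
  attr(out, "n_days") <- length(rows)
  attr(out, "truncated") <- length(rows) < 7L
  out
}

# Internal: weekly (block) anomaly maps for every (year, week), as a
# matrix [n_year_weeks, n_space]; the 7-day window centered on day 4 of
# block w is exactly block w, so block means/sums suffice.
all_week_maps <- function(anoms, mode) {
  nwk <- max(anoms$sday) %/% 7L
  keep <- anoms$sday <= nwk * 7L
  wk <- (anoms$sday[keep] - 1L) %/% 7L + 1L
  key <- sprintf("%06d-%02d", anoms$year[keep], wk)
  M <- rowsum(field_matrix(anoms)[keep, , drop = FALSE], key, reorder = TRUE)
  if (mode == "mean") M <- M / 7
  yrs <- sort(unique(anoms$year))
  yw <- expand.grid(week = seq_len(nwk), year = yrs)[, c(2, 1)]
  yw <- yw[order(yw$year, yw$week), ]
  list(maps = M, year = yw$year, week = yw$week)
}

#' Event composite of surface anomalies with Monte-Carlo significance
#'
#' Averages the event-centered weekly anomaly maps over all events and
#' tests each grid point against a Monte-Carlo null distribution built by
#' repeatedly compositing the same number of randomly drawn non-event
#' weeks; points where the observed composite falls outside the central
#' `conf` interval of the null are flagged significant (two-sided).
#'
#' @param anoms an anomaly [grid_field()].
#' @param events a `wave_events` data frame (at least one event).
#' @param mode `"mean"` (temperature, wind) or `"sum"` (precipitation).
#' @param n_mc number of Monte-Carlo null composites (default 1000).
#' @param conf two-sided confidence level of the significance test.
#' @param seed optional seed for the null draws.
#' @return An object of class `composite_map`: list with `mean` (lat x
#'   lon), `significant` (logical lat x lon), `n_events`, `n_mc`, `lat`,
#'   `lon`, `var`, `units`.
#' @export
composite_map <- function(anoms, events, mode = c("mean", "sum"),
                          n_mc = 1000L, conf = 0.95, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(anoms, "grid_field"))
  if (!nrow(events)) stop("composite_map: no events supplied")
  aw <- all_week_maps(anoms, mode)
  ev_rows <- match(sprintf("%06d-%02d", events$year, events$week),
                   sprintf("%06d-%02d", aw$year, aw$week))
  if (anyNA(ev_rows)) stop("events outside the anomaly data range")
  comp <- colMeans(aw$maps[ev_rows, , drop = FALSE])
  pool <- setdiff(seq_along(aw$year), ev_rows)
  sig <- rep(NA, length(comp))
  if (length(pool) >= length(ev_rows) && n_mc > 0) {
    if (!is.null(seed)) set.seed(seed)
    null <- matrix(0, n_mc, length(comp))
    for (b in seq_len(n_mc)) {
      rows <- sample(pool, length(ev_rows))
      null[b, ] <- colMeans(aw$maps[rows, , drop = FALSE])
    }
    alpha <- (1 - conf) / 2
    lo <- apply(null, 2, stats::quantile, probs = alpha)
    hi <- apply(null, 2, stats::quantile, probs = 1 - alpha)
    sig <- comp < lo | comp > hi
  }
  nlat <- length(anoms$lat)
  structure(list(
    mean = matrix(comp, nlat, length(anoms$lon)),
    significant = matrix(sig, nlat, length(anoms$lon)),
    n_events = length(ev_rows), n_mc = n_mc,
    lat = anoms$lat, lon = anoms$lon,
    var = anoms$var, units = anoms$units),
    class = "composite_map")
}

#' @export
print.composite_map <- function(x, ...) {
  cat(sprintf("<composite_map> %s [%s], %d events, MC n=%d\n",
              x$var, x$units, x$n_events, x$n_mc))
  cat(sprintf("  range %.3g..%.3g, significant fraction %.1f%%\n",
              min(x$mean), max(x$mean),
              100 * mean(x$significant, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.composite_map <- function(x, ...) {
  graphics::image(x$lon, x$lat, t(x$mean), xlab = "longitude",
                  ylab = "latitude", main = sprintf("%s composite", x$var), ...)
  if (!all(is.na(x$significant))) {
    pts <- which(x$significant, arr.ind = TRUE)
    if (nrow(pts))
      graphics::points(x$lon[pts[, 2]], x$lat[pts[, 1]], pch = ".", cex = 1.5)
  }
  invisible(x)
}

#' Belt pattern correlation between two composite maps
#'
#' Area-weighted Pearson correlation and field-versus-field coefficient of
#' determination over a mid-latitude belt (default 38--58N).  Unlike the
#' usual regression R-squared, `r_squared = 1 - sum(w*(a-b)^2) /
#' sum(w*(a-mean_w(a))^2)` compares the two fields directly, with the
#' first argument as the reference; it can be negative and is not
#' symmetric in its arguments.
#'
#' @param a reference `composite_map` (or plain lat x lon matrix).
#' @param b comparison map on the identical grid.
#' @param belt length-2 latitude interval.
#' @param lat,lon grid coordinates, required when `a`/`b` are bare matrices.
#' @return An object of class `pattern_score`: list with `r`, `r_squared`,
#'   `belt`, `n_points`.
#' @export
pattern_correlation <- function(a, b, belt = c(38, 58),
                                lat = NULL, lon = NULL) {
  get_map <- function(x) {
    if (inherits(x, "composite_map")) list(m = x$mean, lat = x$lat)
    else list(m = x, lat = lat)
  }
  A <- get_map(a); B <- get_map(b)
  if (is.null(A$lat)) stop("supply 'lat' when passing bare matrices")
  if (!identical(dim(A$m), dim(B$m))) stop("maps must share an identical grid")
  idx <- which(A$lat >= belt[1] & A$lat <= belt[2])
  if (!length(idx)) stop("no grid latitudes inside the belt")
  wa <- cos(A$lat[idx] * pi / 180)
  va <- A$m[idx, , drop = FALSE]
  vb <- B$m[idx, , drop = FALSE]
  w <- matrix(wa, nrow = length(idx), ncol = ncol(va))
  w <- w / sum(w)
  ma <- sum(w * va); mb <- sum(w * vb)
  va_c <- va - ma; vb_c <- vb - mb
  ssa <- sum(w * va_c^2)
  if (ssa <= 0) stop("zero-variance reference field in the belt")
  ssb <- sum(w * vb_c^2)
  r <- sum(w * va_c * vb_c) / sqrt(ssa * ssb)
  r2 <- 1 - sum(w * (va - vb)^2) / ssa
  structure(list(r = r, r_squared = r2, belt = belt,
                 n_points = length(va)),
            class = "pattern_score")
}

#' @export
print.pattern_score <- function(x, ...) {
  cat(sprintf("<pattern_score> belt %g-%gN: r = %.3f, R2 = %.3f (n = %d)\n",
              x$belt[1], x$belt[2], x$r, x$r_squared, x$n_points))
  invisible(x)
}

#' Region mask from a harvested-area fraction map
#'
#' @param name region name.
#' @param area_fraction lat x lon matrix of harvested-area fraction in
#'   \[0, 1\].
#' @param threshold minimum fraction for a grid point to count (default
#'   0.25).
#' @return An object of class `region_mask` (logical lat x lon matrix with
#'   `name` and `threshold` attributes).
#' @export
region_mask <- function(name, area_fraction, threshold = 0.25) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  m <- area_fraction >= threshold
  if (!any(m))
    stop(sprintf("region '%s': no grid points pass the %.0f%% harvested-area threshold",
                 name, 100 * threshold))
  structure(m, name = name, threshold = threshold, class = "region_mask")
}

#' Longitude-sector region masks for synthetic experiments
#'
#' Splits the longitude circle into equal sectors within a latitude band,
#' a stand-in for harvested-area-based breadbasket masks on synthetic
#' grids.
#'
#' @param field a [grid_field()] supplying the grid.
#' @param names region names (one sector per name).
#' @param band latitude band of the sectors.
#' @return Named list of [region_mask()] objects.
#' @export
sector_masks <- function(field, names = c("NAM", "WEU", "EEU", "IND", "EAS"),
                         band = c(37.5, 57.5)) {
  n <- length(names)
  edges <- seq(0, 360, length.out = n + 1)
  lat_in <- field$lat >= band[1] & field$lat <= band[2]
  out <- lapply(seq_len(n), function(i) {
    lon_in <- field$lon >= edges[i] & field$lon < edges[i + 1]
    m <- outer(lat_in, lon_in)
    structure(m, name = names[i], threshold = 1, class = "region_mask")
  })
  stats::setNames(out, names)
}

#' Regional event-centered anomaly distribution
#'
#' Cosine-latitude-weighted spatial mean of the event-centered weekly
#' anomaly over the masked grid points, one value per event, plus the
#' event mean -- the machinery behind per-region temperature/precipitation
#' anomaly summaries.
#'
#' @param anoms an anomaly [grid_field()].
#' @param events a `wave_events` data frame.
#' @param mask a [region_mask()].
#' @param mode `"mean"` or `"sum"` (see [weekly_anomaly()]).
#' @return An object of class `regional_anomaly`: list with `values`
#'   (data frame year, week, wavenumber, value), `mean`, `region`.
#' @export
regional_anomaly <- function(anoms, events, mask, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(anoms, "grid_field"))
  if (!any(mask))
    stop(sprintf("region '%s': empty mask", attr(mask, "name")))
  if (!nrow(events)) stop("no events supplied")
  wlat <- cos(anoms$lat * pi / 180)
  W <- matrix(wlat, length(anoms$lat), length(anoms$lon))
  W[!mask] <- 0
  W <- W / sum(W)
  vals <- vapply(seq_len(nrow(events)), function(i) {
    m <- weekly_anomaly(anoms, events$year[i], events$center_sday[i], mode)
    sum(W * m)
  }, 0.0)
  structure(list(
    values = data.frame(year = events$year, week = events$week,
                        wavenumber = events$wavenumber, value = vals),
    mean = mean(vals), region = attr(mask, "name")),
    class = "regional_anomaly")
}

#' @export
print.regional_anomaly <- function(x, ...) {
  cat(sprintf("<regional_anomaly> %s: event mean %.3g over %d events\n",
              x$region, x$mean, nrow(x$values)))
  invisible(x)
}

#' Convert precipitation flux to depth per hour
#'
#' Climate-model precipitation comes as a flux in kg m-2 s-1; multiplying
#' by 3.6 converts it to meters per grid cell per hour (1 kg m-2 s-1 =
#' 1 mm/s = 3.6 m/hr).
#'
#' @param field a [grid_field()] whose units are `kg m-2 s-1`.
#' @return The converted [grid_field()] with units `m hr-1`.
#' @export
flux_to_depth <- function(field) {
  stopifnot(inherits(field, "grid_field"))
  ok <- gsub("[[:space:]^/]", "", tolower(field$units)) %in%
    c("kgm-2s-1", "kgm2s1", "kgm-2s1", "kgm2s")
  if (!ok)
    stop(sprintf("expected precipitation flux in 'kg m-2 s-1', got '%s'",
                 field$units))
  grid_field(field$data * 3.6, field$lat, field$lon, field$year,
             field$sday, field$var, "m hr-1")
}
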