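test_that("meridional mean preserves constants and lat-independent structure", {
  fld <- make_field(function(t, la, lo) rep(3.7, length(t)), years = 1)
  zp <- meridional_mean(fld)
  expect_equal(unname(zp$values), matrix(3.7, 92, length(fld$lon)))

  fld2 <- make_field(function(t, la, lo) rep(sin(lo * pi / 180), length(t)),
                     years = 1)
  zp2 <- meridional_mean(fld2)
  expect_equal(unname(zp2$values[1, ]), sin(fld2$lon * pi / 180),
               tolerance = 1e-12)
})

test_that("meridional mean equals the brute-force cos-lat weighted sum", {
  set.seed(42)
  lat <- seq(35, 60, by = 5)
  lon <- seq(0, 330, by = 30)
  fld <- make_field(function(t, la, lo) rnorm(length(t)) + la / 10,
                    years = 1, season_days = 10, lat = lat, lon = lon)
  band <- c(37.5, 57.5)
  zp <- meridional_mean(fld, band)
  idx <- which(lat >= band[1] & lat <= band[2])
  w <- cos(lat[idx] * pi / 180)
  for (t in c(1, 5, 10)) for (j in c(1, 7, 12)) {
    expect_equal(zp$values[t, j],
                 sum(w * fld$data[t, idx, j]) / sum(w), tolerance = 1e-12)
  }
})

test_that("meridional mean rejects bands outside the grid", {
  fld <- make_field(function(t, la, lo) rep(0, length(t)), years = 1,
                    lat = seq(40, 55, by = 5))
  expect_error(meridional_mean(fld, c(37.5, 57.5)), "missing latitudes")
})

test_that("weekly averaging yields 13 blocks with correct means and centers", {
  fld <- make_field(function(t, la, lo) t %% 92, years = 2)
  zw <- weekly_average(meridional_mean(fld))
  expect_equal(sum(zw$year == 1), 13)
  expect_equal(sum(zw$year == 2), 13)
  expect_equal(zw$center_sday, rep((0:12) * 7 + 4, 2))
  # daily values 1..7 in week 1 average to 4
  expect_equal(unname(zw$values[1, 1]), 4)

  cfld <- make_field(function(t, la, lo) rep(2.5, length(t)), years = 1)
  zwc <- weekly_average(meridional_mean(cfld))
  expect_equal(unname(zwc$values), matrix(2.5, 13, length(cfld$lon)))
})

test_that("weekly averaging reports missing season days", {
  fld <- make_field(function(t, la, lo) rep(0, length(t)), years = 1)
  keep <- fld$sday != 40
  broken <- grid_field(fld$data[keep, , , drop = FALSE], fld$lat, fld$lon,
                       fld$year[keep], fld$sday[keep], fld$var, fld$units)
  expect_error(weekly_average(meridional_mean(broken)), "missing season days.*40")
})

test_that("Fourier decomposition recovers pure and mixed sinusoids", {
  lon <- seq(0, 359, by = 1)
  lam <- lon * pi / 180
  mk_weekly <- function(v) {
    structure(list(values = matrix(v, 1), lon = lon, year = 1L, week = 1L,
                   center_sday = 4L), class = "zonal_weekly")
  }
  sp <- fourier_decompose(mk_weekly(8 * cos(5 * lam)), k_max = 10)
  expect_equal(sp$amplitude[sp$wavenumber == 5], 8, tolerance = 1e-12)
  expect_lt(max(sp$amplitude[sp$wavenumber != 5]), 1e-10)
  expect_equal(sp$phase[sp$wavenumber == 5], 0, tolerance = 1e-10)

  sp2 <- fourier_decompose(mk_weekly(3 * cos(5 * lam) + 2 * sin(7 * lam)),
                           k_max = 10)
  expect_equal(sp2$amplitude[sp2$wavenumber == 5], 3, tolerance = 1e-12)
  expect_equal(sp2$amplitude[sp2$wavenumber == 7], 2, tolerance = 1e-12)
  # sin(7x) = cos(7x - pi/2)
  expect_equal(sp2$phase[sp2$wavenumber == 7], pi / 2, tolerance = 1e-10)
})

test_that("Fourier amplitudes match a direct least-squares fit per wavenumber", {
  set.seed(11)
  lon <- seq(0, 350, by = 10)
  lam <- lon * pi / 180
  v <- rnorm(length(lon))
  weekly <- structure(list(values = matrix(v, 1), lon = lon, year = 1L,
                           week = 1L, center_sday = 4L),
                      class = "zonal_weekly")
  sp <- fourier_decompose(weekly, k_max = 8)
  for (k in 1:8) {
    fit <- lm(v ~ cos(k * lam) + sin(k * lam))
    A_ls <- sqrt(sum(coef(fit)[2:3]^2))
    expect_equal(sp$amplitude[sp$wavenumber == k], unname(A_ls),
                 tolerance = 1e-10)
  }
})

test_that("Fourier decomposition rejects bad grids", {
  weekly <- structure(list(values = matrix(0, 1, 10),
                           lon = c(seq(0, 80, 10), 95), year = 1L, week = 1L,
                           center_sday = 4L), class = "zonal_weekly")
  expect_error(fourier_decompose(weekly, 2), "uniform")
  weekly2 <- structure(list(values = matrix(0, 1, 36),
                            lon = seq(0, 350, 10), year = 1L, week = 1L,
                            center_sday = 4L), class = "zonal_weekly")
  expect_error(fourier_decompose(weekly2, 30), "k_max")
})

test_that("climatology mean/SD match direct computation", {
  sp <- data.frame(year = c(1, 2), week = 1, wavenumber = 5,
                   amplitude = c(2, 4))
  cl <- build_climatology(sp)
  expect_equal(cl$mean, 3)
  expect_equal(cl$sd, sd(c(2, 4)))  # sample SD = sqrt(2)
  clp <- build_climatology(sp, sd_type = "population")
  expect_equal(clp$sd, 1)

  set.seed(5)
  sp2 <- data.frame(year = rep(1:4, each = 13), week = rep(1:13, 4),
                    wavenumber = 7, amplitude = rgamma(52, 4))
  cl2 <- build_climatology(sp2)
  expect_equal(cl2$mean, mean(sp2$amplitude))
  expect_equal(cl2$sd, sd(sp2$amplitude))
  expect_equal(cl2$n_weeks, 52L)
})

test_that("event detection applies a strict 1.5-SD exceedance threshold", {
  clim <- data.frame(wavenumber = 5, mean = 10, sd = 2)
  sp <- data.frame(year = 1, week = 1:2, wavenumber = 5,
                   amplitude = c(12.9, 13.1))
  ev <- detect_events(sp, clim)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 13.1)
  expect_equal(ev$center_sday, 11L)

  # SD 0 and amplitude equal to the mean: strict inequality, no event
  clim0 <- data.frame(wavenumber = 5, mean = 10, sd = 0)
  sp0 <- data.frame(year = 1, week = 1, wavenumber = 5, amplitude = 10)
  expect_equal(nrow(detect_events(sp0, clim0)), 0)
  expect_error(detect_events(sp0, clim0, wavenumbers = 7), "not cover")
})

test_that("event count is non-increasing in the detection threshold", {
  set.seed(9)
  sp <- data.frame(year = rep(1:10, each = 13), week = rep(1:13, 10),
                   wavenumber = 5, amplitude = rgamma(130, 3))
  clim <- build_climatology(sp)
  counts <- sapply(seq(0, 3, by = 0.25),
                   function(th) nrow(detect_events(sp, clim, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("calendar classes: multi >= 2, zero = 0, single excluded", {
  ev <- make_events(c(1, 1, 1, 3), c(3, 4, 9, 5))
  cal <- event_calendar(ev, c(1, 4))
  expect_equal(cal$n_events[cal$year == 1], 3L)
  expect_equal(cal$class[cal$year == 1], "multi")
  expect_equal(cal$class[cal$year == 2], "zero")
  expect_equal(cal$class[cal$year == 3], "single")
  expect_equal(calendar_years(cal, 5, "multi"), 1L)
  expect_equal(sort(calendar_years(cal, 5, "zero")), c(2L, 4L))
  # consecutive exceedance weeks count as separate events
  ev2 <- make_events(c(2, 2), c(6, 7))
  cal2 <- event_calendar(ev2, c(1, 2))
  expect_equal(cal2$n_events[cal2$year == 2], 2L)
  expect_equal(cal2$class[cal2$year == 2], "multi")
})
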