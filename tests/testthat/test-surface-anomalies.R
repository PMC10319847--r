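test_that("detrending removes pure trends and pure seasonal cycles", {
  trendy <- make_field(function(t, la, lo) 280 + 0.01 * t, years = 3)
  a1 <- detrend_field(trendy)
  expect_lt(max(abs(a1$data)), 1e-9)

  seasonal <- make_field(function(t, la, lo) {
    s <- (t - 1) %% 92 + 1
    280 + 5 * sin(2 * pi * s / 92)
  }, years = 3)
  a2 <- detrend_field(seasonal)
  expect_lt(max(abs(a2$data)), 1e-9)
})

test_that("detrended anomalies have exactly zero day-of-season means", {
  set.seed(3)
  fld <- make_field(function(t, la, lo) rnorm(length(t), 280), years = 4,
                    season_days = 10, lat = c(40, 45), lon = c(0, 90, 180))
  an <- detrend_field(fld)
  for (s in 1:10) {
    sub <- an$data[an$sday == s, , , drop = FALSE]
    expect_lt(max(abs(apply(sub, c(2, 3), mean))), 1e-10)
  }
})

test_that("detrending matches a per-gridpoint lm oracle on trend+cycle+spike", {
  set.seed(13)
  years <- 4; sd_n <- 10
  fld <- make_field(function(t, la, lo) {
    s <- (t - 1) %% sd_n + 1
    280 + 0.02 * t + 3 * cos(2 * pi * s / sd_n) + la / 50
  }, years = years, season_days = sd_n, lat = c(40, 50), lon = c(0, 180))
  fld$data[25, 1, 1] <- fld$data[25, 1, 1] + 5   # spike: year 3, sday 5
  an <- detrend_field(fld)
  # oracle: lm residuals then day-of-season mean removal, per gridpoint
  for (i in 1:2) for (j in 1:2) {
    y <- fld$data[, i, j]
    yr <- fld$year
    r <- y - (mean(y) + coef(lm(y ~ yr))[2] * (yr - mean(yr)))
    s <- fld$sday
    r <- r - ave(r, s)
    expect_equal(an$data[, i, j], r, tolerance = 1e-10)
  }
  # spike survives detrending at (nearly) full magnitude
  expect_gt(an$data[25, 1, 1], 3.5)
})

test_that("weekly anomaly windows average and aggregate correctly", {
  fld <- make_field(function(t, la, lo) rep(1.5, length(t)), years = 1)
  expect_equal(unname(weekly_anomaly(fld, 1, 10, "mean")[1, 1]), 1.5)
  expect_equal(unname(weekly_anomaly(fld, 1, 10, "sum")[1, 1]), 10.5)

  set.seed(8)
  fld2 <- make_field(function(t, la, lo) rnorm(length(t)), years = 1)
  m <- weekly_anomaly(fld2, 1, 20, "mean")
  s <- weekly_anomaly(fld2, 1, 20, "sum")
  win <- fld2$data[17:23, 1, 1]
  expect_equal(unname(m[1, 1]), mean(win), tolerance = 1e-12)
  expect_equal(unname(s[1, 1]), sum(win), tolerance = 1e-12)
  expect_false(attr(m, "truncated"))

  tr <- weekly_anomaly(fld2, 1, 2, "mean")   # window hits the season start
  expect_true(attr(tr, "truncated"))
  expect_equal(attr(tr, "n_days"), 5L)
  expect_equal(unname(tr[1, 1]), mean(fld2$data[1:5, 1, 1]), tolerance = 1e-12)
})

test_that("a single-event composite is that event's weekly anomaly map", {
  set.seed(17)
  fld <- make_field(function(t, la, lo) rnorm(length(t)), years = 2)
  an <- detrend_field(fld)
  ev <- make_events(2, 6)
  cm <- composite_map(an, ev, "mean", n_mc = 0)
  expect_equal(cm$mean, weekly_anomaly(an, 2, ev$center_sday, "mean"),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(composite_map(an, ev[0, ], "mean"), "no events")
})

test_that("composite over all weeks of centered anomalies is about zero", {
  set.seed(19)
  fld <- make_field(function(t, la, lo) rnorm(length(t), 280), years = 3)
  an <- detrend_field(fld)
  allev <- make_events(rep(1:3, each = 13), rep(1:13, 3))
  cm <- composite_map(an, allev, "mean", n_mc = 0)
  expect_lt(max(abs(cm$mean)), 1e-10)
})

test_that("significance mask has roughly nominal type-I error on null data", {
  cfg <- fast_config(years = 15, coupling_temp = 0,
                     noise_sd = list(wind = 0, temp = 0.5), seed = 23)
  w <- gen_wind_field(cfg)
  s <- gen_surface_fields(cfg, w)
  an <- detrend_field(s$temp)
  ev <- make_events(c(2, 5, 9, 12, 14), c(3, 7, 11, 2, 8))
  cm <- composite_map(an, ev, "mean", n_mc = 400, seed = 99)
  frac <- mean(cm$significant)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.15)
})

test_that("pattern correlation behaves on identical, flipped and known fields", {
  set.seed(29)
  lat <- seq(38, 58, by = 10)
  m <- matrix(rnorm(3 * 8), 3, 8)
  ps <- pattern_correlation(m, m, lat = lat)
  expect_equal(ps$r, 1)
  expect_equal(ps$r_squared, 1)

  ps2 <- pattern_correlation(m, -m, lat = lat)
  expect_equal(ps2$r, -1)
  expect_lt(ps2$r_squared, 0)

  # hand-computed 2x2 example at lat 40/50N
  a <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- matrix(c(2, 1, 4, 3), 2, 2)
  w <- c(cos(40 * pi / 180), cos(50 * pi / 180))
  w <- rep(w, 2) / (2 * sum(w))
  ma <- sum(w * a); mb <- sum(w * b)
  r_hand <- sum(w * (a - ma) * (b - mb)) /
    sqrt(sum(w * (a - ma)^2) * sum(w * (b - mb)^2))
  r2_hand <- 1 - sum(w * (a - b)^2) / sum(w * (a - ma)^2)
  ps3 <- pattern_correlation(a, b, lat = c(40, 50))
  expect_equal(ps3$r, r_hand, tolerance = 1e-12)
  expect_equal(ps3$r_squared, r2_hand, tolerance = 1e-12)

  # r is symmetric, the field-vs-field R2 is not
  ps5 <- pattern_correlation(a, 2 * a, lat = c(40, 50))
  ps6 <- pattern_correlation(2 * a, a, lat = c(40, 50))
  expect_equal(ps6$r, ps5$r)
  expect_false(isTRUE(all.equal(ps6$r_squared, ps5$r_squared)))

  expect_error(pattern_correlation(matrix(1, 2, 2), a, lat = c(40, 50)),
               "zero-variance")
})

test_that("regional anomalies reduce correctly under trivial masks", {
  fld <- make_field(function(t, la, lo) rep(2.2, length(t)), years = 1)
  an <- fld  # already "anomalies" for this purpose
  ev <- make_events(1, 5)
  full <- structure(matrix(TRUE, length(fld$lat), length(fld$lon)),
                    name = "ALL", class = "region_mask")
  ra <- regional_anomaly(an, ev, full, "mean")
  expect_equal(ra$mean, 2.2)

  one <- structure(matrix(FALSE, length(fld$lat), length(fld$lon)),
                   name = "PT", class = "region_mask")
  one[3, 7] <- TRUE
  set.seed(31)
  fld2 <- make_field(function(t, la, lo) rnorm(length(t)), years = 1)
  ra2 <- regional_anomaly(fld2, ev, one, "mean")
  expect_equal(ra2$values$value,
               unname(weekly_anomaly(fld2, 1, ev$center_sday, "mean")[3, 7]),
               tolerance = 1e-12)

  empty <- structure(matrix(FALSE, length(fld$lat), length(fld$lon)),
                     name = "VOID", class = "region_mask")
  expect_error(regional_anomaly(an, ev, empty), "VOID")
})

test_that("region masks enforce the harvested-area threshold", {
  af <- matrix(c(0.3, 0.1, 0.26, 0.24), 2, 2)
  m <- region_mask("WEU", af, 0.25)
  expect_equal(sum(m), 2)
  expect_error(region_mask("EEU", matrix(0.1, 2, 2), 0.25), "EEU")
  expect_error(region_mask("X", af, 0), "threshold")
})

test_that("precipitation flux converts to depth by the factor 3.6", {
  mk <- function(vals) {
    grid_field(array(vals, c(1, 1, length(vals))), 45,
               seq(0, 350, length.out = length(vals))[seq_along(vals)],
               1L, 1L, "pr", "kg m-2 s-1")
  }
  f <- mk(c(1, 0, 0.5))
  out <- flux_to_depth(f)
  expect_equal(as.vector(out$data), c(3.6, 0, 1.8))
  expect_equal(out$units, "m hr-1")
  bad <- grid_field(array(1, c(1, 1, 1)), 45, 0, 1L, 1L, "pr", "mm day-1")
  expect_error(flux_to_depth(bad), "kg m-2 s-1")
})
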