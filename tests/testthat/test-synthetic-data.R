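test_that("identical configs reproduce identical outputs bit for bit", {
  cfg <- fast_config(years = 12, seed = 101)
  a <- gen_wind_field(cfg)
  b <- gen_wind_field(cfg)
  expect_identical(a$field$data, b$field$data)
  expect_identical(a$truth$events, b$truth$events)
  sa <- gen_surface_fields(cfg, a)
  sb <- gen_surface_fields(cfg, b)
  expect_identical(sa$temp$data, sb$temp$data)
  ya <- gen_yield_series(cfg, a$truth)
  yb <- gen_yield_series(cfg, b$truth)
  expect_identical(ya$yields, yb$yields)
})

test_that("a config requires a seed and valid parameters", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(years = 5, seed = 1), "years")
  expect_error(sim_config(event_rate = -1, seed = 1), "event_rate")
  expect_error(sim_config(event_effect = 1, seed = 1), "event_effect")
  expect_error(sim_config(base_amplitude_sd = -1, seed = 1), "SD")
})

test_that("degenerate no-event config yields zero detectable events", {
  cfg <- fast_config(years = 10, event_rate = 0, base_amplitude_sd = 0,
                     noise_sd = list(wind = 0), seed = 3)
  w <- gen_wind_field(cfg)
  expect_equal(nrow(w$truth$events), 0)
  sp <- fourier_decompose(weekly_average(meridional_mean(w$field)), k_max = 8)
  cl <- build_climatology(sp)
  ev <- detect_events(sp, cl, wavenumbers = c(5, 7))
  expect_equal(nrow(ev), 0)
})

test_that("explicitly planted event weeks are exactly what the detector finds", {
  pw <- data.frame(year = 5, week = c(3, 9), wavenumber = 7)
  cfg <- fast_config(years = 10, planted_weeks = pw, base_amplitude_sd = 0,
                     noise_sd = list(wind = 0), seed = 4)
  w <- gen_wind_field(cfg)
  sp <- fourier_decompose(weekly_average(meridional_mean(w$field)), k_max = 8)
  ev <- detect_events(sp, build_climatology(sp), wavenumbers = 7)
  expect_equal(ev$year, c(5, 5))
  expect_equal(ev$week, c(3, 9))
})

test_that("a pure standing wave produces the exact Fourier identity", {
  cfg <- fast_config(years = 10, wavenumbers = 5, base_amplitude_mean = 8,
                     base_amplitude_sd = 0, event_rate = 0,
                     noise_sd = list(wind = 0), seed = 6)
  w <- gen_wind_field(cfg)
  sp <- fourier_decompose(weekly_average(meridional_mean(w$field)), k_max = 10)
  expect_equal(sp$amplitude[sp$wavenumber == 5], rep(8, 130),
               tolerance = 1e-10)
  expect_lt(max(sp$amplitude[sp$wavenumber != 5]), 1e-9)
})

test_that("doubling the planted amplitude doubles the diagnosed amplitude", {
  base <- list(years = 10, wavenumbers = 5, base_amplitude_sd = 0,
               event_rate = 0, noise_sd = list(wind = 0), seed = 8)
  a1 <- do.call(fast_config, c(base, base_amplitude_mean = 3))
  a2 <- do.call(fast_config, c(base, base_amplitude_mean = 6))
  amp <- function(cfg) {
    sp <- fourier_decompose(weekly_average(meridional_mean(
      gen_wind_field(cfg)$field)), k_max = 5)
    sp$amplitude[sp$wavenumber == 5]
  }
  expect_equal(amp(a2), 2 * amp(a1), tolerance = 1e-10)
})

test_that("ground-truth events are exactly the threshold exceedances", {
  cfg <- fast_config(years = 15, seed = 12)
  w <- gen_wind_field(cfg)
  tr <- w$truth
  for (i in seq_along(cfg$wavenumbers)) {
    A <- tr$amplitude[, , i]
    thr <- tr$climatology$mean[i] + 1.5 * tr$climatology$sd[i]
    hits <- which(A > thr, arr.ind = TRUE)
    evk <- tr$events[tr$events$wavenumber == cfg$wavenumbers[i], ]
    expect_equal(nrow(evk), nrow(hits))
    expect_setequal(paste(evk$year, evk$week),
                    paste(hits[, 1], hits[, 2]))
  }
})

test_that("zero temperature coupling gives a null event composite", {
  cfg <- fast_config(years = 15, coupling_temp = 0,
                     noise_sd = list(wind = 0, temp = 0.3), seed = 21)
  w <- gen_wind_field(cfg)
  s <- gen_surface_fields(cfg, w)
  ta <- detrend_field(s$temp)
  ev <- make_events(w$truth$events$year, w$truth$events$week)
  cm <- composite_map(ta, ev, "mean", n_mc = 0)
  # composite of pure noise: SE ~ 0.3/sqrt(7*n_events) per gridpoint
  se <- 0.3 / sqrt(7 * nrow(ev))
  expect_lt(max(abs(cm$mean)), 6 * se)
})

test_that("noise-free surface composite equals the planted ridge pattern", {
  pw <- data.frame(year = c(4, 9), week = c(5, 11), wavenumber = 5)
  cfg <- fast_config(years = 12, wavenumbers = 5, planted_weeks = pw,
                     base_amplitude_mean = 0, base_amplitude_sd = 0,
                     coupling_temp = 1.2,
                     noise_sd = list(wind = 0, temp = 0, precip = 0),
                     seed = 31)
  w <- gen_wind_field(cfg)
  s <- gen_surface_fields(cfg, w)
  ta <- detrend_field(s$temp)
  ev <- make_events(pw$year, pw$week)
  cm <- composite_map(ta, ev, "mean", n_mc = 0)
  # oracle: coupling * (event-mean ridge pattern minus its own share of the
  # day-in-season climatology, which the detrending removed)
  P <- waveyield:::ridge_pattern_matrix(s$truth)
  nw <- 13
  rows <- (pw$year - 1) * nw + pw$week
  expected_lonprof <- numeric(length(cfg$lon))
  for (r in rows) {
    # climatological share at this week's season days: mean over years
    yr_rows <- ((seq_len(cfg$years) - 1) * nw) + (r - 1) %% nw + 1
    expected_lonprof <- expected_lonprof +
      1.2 * (P[r, ] - colMeans(P[yr_rows, , drop = FALSE])) / length(rows)
  }
  for (i in seq_along(cfg$lat))
    expect_equal(unname(cm$mean[i, ]), expected_lonprof, tolerance = 1e-9)
})

test_that("generated precipitation is non-negative for any seed", {
  for (seed in c(1, 77, 1234)) {
    cfg <- fast_config(years = 10, seed = seed,
                       noise_sd = list(precip = 2))
    w <- gen_wind_field(cfg)
    s <- gen_surface_fields(cfg, w)
    expect_gte(min(s$precip$data), 0)
  }
})

test_that("pure-trend zero-noise yields give near-zero SSA anomalies", {
  cfg <- fast_config(years = 40, event_effect = 0,
                     noise_sd = list(yield = 0), seed = 41)
  tr <- gen_wave_spectrum(cfg)$truth
  ys <- gen_yield_series(cfg, tr)
  d <- ys$yields[ys$yields$region == "NAM", ]
  an <- ssa_detrend(d$yield)$anomaly
  expect_lt(max(abs(an)), 0.01)
})

test_that("generative contingency reproduces the closed-form implied LMF", {
  cfg <- fast_config(years = 4000, event_effect = 0.05, concurrence = 0.5,
                     noise_sd = list(yield = 0.05), seed = 55)
  tr <- gen_wave_spectrum(cfg)$truth
  ys <- gen_yield_series(cfg, tr)
  # classify against the TRUE trend (the closed form conditions on it)
  low <- sapply(split(ys$yields, ys$yields$region), function(d) {
    trend <- cfg$yield_trend[[1]][1] + cfg$yield_trend[[1]][2] * (d$year - 1)
    d$yield < trend
  })
  # direct counting of the contingency for one pair
  m <- ys$truth$multi_years; z <- ys$truth$zero_years
  joint <- low[, 1] & low[, 2]
  lmf_count <- (sum(joint[m]) / length(m)) / (sum(joint[z]) / length(z))
  expect_equal(lmf_count, ys$truth$implied_lmf_low, tolerance = 0.15)
  expect_gt(ys$truth$implied_lmf_low, 1)  # planted concurrence raises it
})

test_that("independence design implies LMF of one", {
  cfg <- fast_config(years = 20, event_effect = 0, concurrence = 0, seed = 61)
  tr <- gen_wave_spectrum(cfg)$truth
  ys <- gen_yield_series(cfg, tr)
  expect_equal(ys$truth$implied_lmf_low, 1, tolerance = 1e-6)
  expect_equal(ys$truth$implied_lmf_high, 1, tolerance = 1e-6)
})
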