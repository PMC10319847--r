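#' Run the full synthetic-to-LMF analysis pipeline
#'
#' Orchestrates every stage on one synthetic dataset: generate wind,
#' surface and yield data from a [sim_config()]; detect wave events
#' (meridional mean, weekly averaging, Fourier decomposition, climatology,
#' 1.5-SD exceedance); build temperature and precipitation event
#' composites; estimate regional composite yield anomalies for multi- and
#' zero-event years with the subsample bootstrap; classify years against
#' the SSA trend and compute the pairwise LMF grid with permutation
#' significance.  Every intermediate artifact is written to `out_dir`
#' (NetCDF for fields, CSV for tables) together with a machine-readable
#' JSON manifest carrying the configuration, its hash, all seeds, and the
#' file list.  Re-running the same configuration reproduces all outputs
#' bit-exactly.
#'
#' @param config a [sim_config()] (the seed it carries drives every
#'   stochastic stage).
#' @param out_dir output directory, created if needed.
#' @param n_rep bootstrap replicates per composite (default 500).
#' @param n_perm permutations for the LMF low/high test (default 499).
#' @param n_mc Monte-Carlo draws for composite-map significance (default
#'   200).
#' @param write_fields write the (possibly large) daily fields to NetCDF
#'   (default TRUE).
#' @return Invisibly, a list with the key results: `events`, `calendar`,
#'   `composites` (per wavenumber, temperature and precipitation maps),
#'   `yield_composites`, `lmf`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, n_rep = 500L, n_perm = 499L,
                         n_mc = 200L, write_fields = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop("pipeline refused: config carries no seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  wind <- stage("simulate-wind", gen_wind_field(config))
  surf <- stage("simulate-surface", gen_surface_fields(config, wind))
  ysim <- stage("simulate-yields", gen_yield_series(config, wind$truth))

  spectra <- stage("detect", {
    prof <- meridional_mean(wind$field)
    fourier_decompose(weekly_average(prof),
                      k_max = max(config$wavenumbers))
  })
  clim <- stage("detect", build_climatology(spectra))
  events <- stage("detect", detect_events(spectra, clim,
                                          wavenumbers = config$wavenumbers))
  calendar <- stage("detect", event_calendar(events,
                                             c(1, config$years),
                                             config$wavenumbers))

  t_anom <- stage("composite", detrend_field(surf$temp))
  p_anom <- stage("composite", detrend_field(surf$precip))
  composites <- lapply(config$wavenumbers, function(k) {
    ek <- events[events$wavenumber == k, ]
    if (!nrow(ek)) return(NULL)
    list(temp = composite_map(t_anom, ek, "mean", n_mc = n_mc,
                              seed = config$seed + 10L + k),
         precip = composite_map(p_anom, ek, "sum", n_mc = n_mc,
                                seed = config$seed + 20L + k))
  })
  names(composites) <- paste0("wave", config$wavenumbers)

  yields <- ysim$yields
  yc <- stage("yields", do.call(rbind, lapply(config$wavenumbers, function(k) {
    do.call(rbind, lapply(c("multi", "zero"), function(g)
      tryCatch(composite_yield(yields, calendar, k, g),
               error = function(e) NULL)))
  })))
  boots <- stage("yields", {
    ks <- config$wavenumbers
    out <- list()
    for (k in ks) for (r in config$regions) {
      b <- tryCatch(
        bootstrap_composite(yields, calendar, k, "contrast", region = r,
                            n_rep = n_rep, seed = config$seed + 100L),
        error = function(e) NULL)
      if (!is.null(b))
        out[[length(out) + 1L]] <- data.frame(
          region = r, wavenumber = k, estimate = b$point,
          ci_lo = confint(b)[1], ci_hi = confint(b)[2],
          n_multi = b$n[1], n_zero = b$n[2])
    }
    do.call(rbind, out)
  })

  signs_lmf <- stage("lmf", {
    an <- do.call(rbind, lapply(split(yields, yields$region), function(d) {
      data.frame(region = d$region[1], year = d$year,
                 anomaly = ssa_detrend(d$yield)$anomaly)
    }))
    signs <- classify_years(an)
    res <- do.call(rbind, lapply(config$wavenumbers, function(k) {
      m <- lmf_matrix(signs, calendar, k)
      m$p_low_vs_high <- vapply(seq_len(nrow(m)), function(i) {
        if (m$mode[i] != "low") return(NA_real_)
        lmf_significance(signs, calendar,
                         c(m$region_a[i], m$region_b[i]), k,
                         n_perm = n_perm,
                         seed = config$seed + 200L)$p_value
      }, 0.0)
      m
    }))
    res
  })

  wcsv <- function(obj, fname) {
    p <- file.path(out_dir, fname)
    utils::write.csv(as.data.frame(obj), p, row.names = FALSE)
    files <<- c(files, fname)
    p
  }
  if (write_fields) {
    for (nm in c("v250", "t2m", "pr")) {
      f <- switch(nm, v250 = wind$field, t2m = surf$temp, pr = surf$precip)
      write_gridded(f, file.path(out_dir, paste0(nm, ".nc")),
                    attrs = list(config_hash = hash))
      files <- c(files, paste0(nm, ".nc"))
    }
  }
  wcsv(spectra, "spectra.csv")
  write_events_csv(events, file.path(out_dir, "events.csv"))
  files <- c(files, "events.csv")
  wcsv(calendar, "event_calendar.csv")
  wcsv(yields, "yields.csv")
  if (!is.null(yc)) wcsv(yc, "yield_composites.csv")
  if (!is.null(boots)) wcsv(boots, "yield_bootstrap.csv")
  wcsv(signs_lmf, "lmf.csv")

  # per-year event counts per wavenumber, the standard run diagnostic
  counts <- summary.event_calendar(calendar)
  manifest <- list(
    package = "waveyield",
    version = as.character(utils::packageVersion("waveyield")),
    config = unclass(config)[setdiff(names(config), c("lat", "lon"))],
    config_hash = hash,
    seeds = list(simulation = config$seed,
                 composites = config$seed + 10L,
                 bootstrap = config$seed + 100L,
                 permutation = config$seed + 200L),
    event_summary = counts,
    files = files)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(events = events, calendar = calendar,
                 composites = composites, yield_composites = yc,
                 yield_bootstrap = boots, lmf = signs_lmf,
                 manifest = manifest))
}
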