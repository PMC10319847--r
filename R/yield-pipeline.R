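#' Aggregate national crop tables to a region
#'
#' Regional yield per year is total production divided by total harvested
#' area, pooling member units (countries or grid cells) and, when a `crop`
#' column is present, crops (combined wheat+maize series pool production
#' and area before any detrending).
#'
#' @param table data frame with columns `unit` (or `region`/`country`),
#'   `year`, `production`, `area`, optionally `crop`.
#' @param members character vector of member units to pool.
#' @param name region name for the output.
#' @return A data frame (region, year, production, area, yield); years
#'   with missing member units are flagged via the `"gap_years"`
#'   attribute.
#' @export
aggregate_region <- function(table, members, name) {
  unit_col <- intersect(c("unit", "country", "region"), names(table))[1]
  if (is.na(unit_col)) stop("no unit/country/region column in 'table'")
  stopifnot(all(c("year", "production", "area") %in% names(table)))
  tb <- table[table[[unit_col]] %in% members, ]
  if (!nrow(tb)) stop(sprintf("no rows for region '%s' members", name))
  present <- tapply(tb[[unit_col]], tb$year,
                    function(u) length(unique(u)))
  gaps <- as.integer(names(present))[present < length(members)]
  prod <- tapply(tb$production, tb$year, sum)
  area <- tapply(tb$area, tb$year, sum)
  if (any(area == 0)) stop(sprintf("region '%s': zero total area", name))
  out <- data.frame(region = name, year = as.integer(names(prod)),
                    production = as.vector(prod), area = as.vector(area),
                    yield = as.vector(prod) / as.vector(area))
  rownames(out) <- NULL
  if (length(gaps)) {
    warning(sprintf("region '%s': missing member units in years %s",
                    name, paste(gaps, collapse = ", ")))
    attr(out, "gap_years") <- gaps
  }
  out
}

# Internal: diagonal averaging (Hankelization) of a rank-1 term of the
# trajectory matrix back to a series of length N.
diag_average <- function(E, N) {
  L <- nrow(E); K <- ncol(E)
  out <- numeric(N)
  cnt <- numeric(N)
  for (i in seq_len(L)) {
    idx <- i:(i + K - 1)
    out[idx] <- out[idx] + E[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  out / cnt
}

#' Singular-spectrum-analysis yield detrending
#'
#' Extracts a smooth nonparametric trend by embedding the annual series in
#' an `L`-lagged trajectory matrix (default L = 10 years, so anomalies are
#' measured relative to roughly 10-year moving windows), taking its SVD,
#' and summing the eigentriples whose reconstructed components are
#' low-frequency (a dominant share of spectral power at periods longer
#' than `L`).  The fractional anomaly is `yield/trend - 1`.  Series
#' shorter than `2*L` fall back to a LOESS local-linear trend of
#' comparable bandwidth, flagged in the output.
#'
#' @param y numeric series of annual yields (t/ha), strictly positive.
#' @param L embedding window length in years (default 10).
#' @param low_freq_share minimum share of a component's spectral power at
#'   frequencies below `1/L` for it to count as trend (default 0.75).
#' @return An object of class `ssa_trend`: list with `trend`, `anomaly`,
#'   `method` (`"ssa"` or `"loess"`), `components` (selected eigentriple
#'   indices).
#' @export
ssa_detrend <- function(y, L = 10L, low_freq_share = 0.75) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  N <- length(y)
  L <- as.integer(L)
  if (N < 2L * L) {
    span <- min(1, max(0.3, (L + 2) / N))
    fit <- stats::loess(y ~ t, data = data.frame(y = y, t = seq_len(N)),
                        span = span, degree = 1)
    trend <- stats::predict(fit)
    if (any(trend <= 0)) stop("estimated trend is not positive")
    return(structure(list(trend = trend, anomaly = y / trend - 1,
                          method = "loess", components = integer()),
                     class = "ssa_trend"))
  }
  K <- N - L + 1L
  X <- vapply(seq_len(K), function(i) y[i:(i + L - 1L)], numeric(L))
  sv <- svd(X)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  freqs <- seq(0, N - 1) / N
  low <- freqs < 1 / L | freqs > 1 - 1 / L
  selected <- integer()
  rcs <- matrix(0, N, r)
  for (i in seq_len(r)) {
    E <- sv$d[i] * tcrossprod(sv$u[, i], sv$v[, i])
    rc <- diag_average(E, N)
    rcs[, i] <- rc
    P <- Mod(stats::fft(rc))^2
    if (sum(P[low]) / sum(P) >= low_freq_share) selected <- c(selected, i)
  }
  if (!length(selected)) selected <- 1L
  trend <- rowSums(rcs[, selected, drop = FALSE])
  if (any(trend <= 0)) stop("estimated trend is not positive")
  structure(list(trend = trend, anomaly = y / trend - 1,
                 method = "ssa", components = selected),
            class = "ssa_trend")
}

#' @export
print.ssa_trend <- function(x, ...) {
  cat(sprintf("<ssa_trend> %s, %d years, components {%s}, anomaly sd %.3f\n",
              x$method, length(x$trend),
              paste(x$components, collapse = ","), stats::sd(x$anomaly)))
  invisible(x)
}

#' Standardize an event-year yield by its +-3-year neighborhood
#'
#' Divides the yield of a given year by the mean yield of the three years
#' preceding and following it, expressing the event year as a fraction of
#' contemporaneous regional production.  Near the series boundary the
#' window shrinks to the available years; if fewer than `min_neighbors`
#' neighbor years remain, or all neighbors fall on one side, the year is
#' excluded (NA) and flagged.
#'
#' @param yield numeric yields indexed by `years`.
#' @param years integer years matching `yield`.
#' @param event_year the year to standardize.
#' @param min_neighbors minimum neighbor years required (default 3).
#' @return Standardized yield (1 = at neighborhood level) with attribute
#'   `n_neighbors`; NA if the window is inadmissible.
#' @export
normalize_event_yield <- function(yield, years, event_year,
                                  min_neighbors = 3L) {
  stopifnot(length(yield) == length(years))
  i <- match(event_year, years)
  if (is.na(i)) stop(sprintf("year %d not in series", event_year))
  pre <- years >= event_year - 3L & years <= event_year - 1L
  post <- years >= event_year + 1L & years <= event_year + 3L
  nb <- yield[pre | post]
  if (!any(pre) || !any(post) || length(nb) < min_neighbors)
    return(structure(NA_real_, n_neighbors = length(nb)))
  structure(yield[i] / mean(nb), n_neighbors = length(nb))
}

# Internal: per-year composite anomalies (%) for one region's series.
standardized_anomalies <- function(yield, years, group_years,
                                   method = c("standardized", "ssa"),
                                   ssa_window = 10L) {
  method <- match.arg(method)
  if (method == "ssa") {
    an <- ssa_detrend(yield, L = ssa_window)$anomaly * 100
    return(an[match(group_years, years)])
  }
  vapply(group_years, function(gy)
    100 * (as.numeric(normalize_event_yield(yield, years, gy)) - 1), 0.0)
}

#' Composite yield anomaly for multi-event or zero-event years
#'
#' Mean standardized yield anomaly (% of contemporaneous regional
#' production, via the +-3-year neighborhood standardization by default)
#' across the years of a calendar class, per region.
#'
#' @param yields data frame (region, year, yield).
#' @param calendar an [event_calendar()].
#' @param wavenumber wavenumber whose calendar classes are used.
#' @param group `"multi"` or `"zero"` (the control).
#' @param method `"standardized"` (+-3-year window) or `"ssa"`
#'   (SSA-trend-relative anomalies).
#' @return Data frame (region, wavenumber, group, estimate, n_years).
#' @export
composite_yield <- function(yields, calendar, wavenumber,
                            group = c("multi", "zero"),
                            method = c("standardized", "ssa")) {
  group <- match.arg(group)
  method <- match.arg(method)
  gy <- calendar_years(calendar, wavenumber, group)
  out <- do.call(rbind, lapply(split(yields, yields$region), function(d) {
    g <- intersect(gy, d$year)
    if (!length(g))
      stop(sprintf("empty %s-event group for region '%s', wavenumber %d",
                   group, d$region[1], wavenumber))
    an <- standardized_anomalies(d$yield, d$year, g, method)
    data.frame(region = d$region[1], wavenumber = wavenumber, group = group,
               estimate = mean(an, na.rm = TRUE),
               n_years = sum(!is.na(an)))
  }))
  rownames(out) <- NULL
  out
}

#' Subsample-bootstrap distribution of a composite yield anomaly
#'
#' Re-estimates the composite `n_rep` times (default 500) from random
#' subsamples of about 90% of the group sample, drawn without replacement,
#' yielding the replicate distribution whose median is the reported point
#' estimate.  Because the +-3-year standardization windows of group years
#' closer than 7 years overlap (their anomalies share neighbor yields and
#' are therefore serially dependent), the unit of resampling is the
#' cluster of window-overlapping group years, not the single year.  With
#' `group = "contrast"` each replicate is the difference between an
#' independently subsampled multi-event and zero-event composite -- the
#' neighbor-contamination-free estimate of the event effect.
#'
#' @param yields data frame (region, year, yield) for one region (or
#'   filtered via `region`).
#' @param calendar an [event_calendar()].
#' @param wavenumber wavenumber of interest.
#' @param group `"multi"`, `"zero"`, or `"contrast"` (multi minus zero).
#' @param region region to use when `yields` holds several.
#' @param n_rep number of replicates (default 500).
#' @param keep_frac subsample fraction (default 0.9); at least one year is
#'   always left out so replicates have spread.
#' @param method anomaly route, see [composite_yield()].
#' @param seed optional seed, recorded in the result.
#' @return An object of class `yield_boot`: replicates, point estimate
#'   (median), per-group sizes, and the ingredients for [confint()].
#' @export
bootstrap_composite <- function(yields, calendar, wavenumber,
                                group = c("multi", "zero", "contrast"),
                                region = NULL, n_rep = 500L,
                                keep_frac = 0.9,
                                method = c("standardized", "ssa"),
                                seed = NULL) {
  group <- match.arg(group)
  method <- match.arg(method)
  if (!is.null(region)) yields <- yields[yields$region == region, ]
  if (length(unique(yields$region)) != 1L)
    stop("supply a single region (or use the 'region' argument)")
  if (!is.null(seed)) set.seed(seed)
  groups <- if (group == "contrast") c("multi", "zero") else group
  an <- lapply(groups, function(g) {
    gy <- intersect(calendar_years(calendar, wavenumber, g), yields$year)
    if (length(gy) < 2L)
      stop(sprintf("group '%s' needs >= 2 years (region '%s', wavenumber %d)",
                   g, yields$region[1], wavenumber))
    a <- standardized_anomalies(yields$yield, yields$year, gy, method)
    names(a) <- gy
    a[!is.na(a)]
  })
  names(an) <- groups
  # resampling unit: contiguous 7-year calendar blocks (the diameter of
  # the +-3-year standardization window), so the replicate spread stays
  # honest under the serial dependence the overlapping windows induce
  clusters <- lapply(an, function(a) {
    yrs <- as.integer(names(a))
    split(a, (yrs - 1L) %/% 7L)
  })
  n_cl <- vapply(clusters, length, 0L)
  if (any(n_cl < 2L))
    stop("too few independent year clusters to subsample")
  m <- vapply(clusters, function(cl)
    as.integer(min(ceiling(keep_frac * length(cl)), length(cl) - 1L)), 0L)
  reps <- matrix(0, n_rep, length(groups))
  for (b in seq_len(n_rep))
    for (g in seq_along(groups))
      reps[b, g] <- mean(unlist(clusters[[g]][sample(n_cl[g], m[g])]))
  f_nb <- NA_real_
  if (group == "contrast") {
    # plug-in correction for window contamination: the raw contrast
    # estimates -e/(1 - e*f), with f the multi-event fraction inside the
    # +-3-year windows; f is observable from the calendar, so invert
    multi_set <- calendar_years(calendar, wavenumber, "multi")
    all_gy <- as.integer(unlist(lapply(clusters, function(cl)
      names(unlist(unname(cl))))))
    yr_rng <- range(yields$year)
    f_nb <- mean(vapply(all_gy, function(y) {
      nb <- setdiff(max(yr_rng[1], y - 3L):min(yr_rng[2], y + 3L), y)
      mean(nb %in% multi_set)
    }, 0.0))
    craw <- (reps[, 1] - reps[, 2]) / 100
    replicates <- 100 * craw / (1 - craw * f_nb)
  } else {
    replicates <- reps[, 1]
  }
  raw_replicates <- if (group == "contrast") reps[, 1] - reps[, 2]
                    else reps[, 1]
  structure(list(
    replicates = replicates, raw_replicates = raw_replicates,
    group_replicates = reps,
    point = stats::median(replicates),
    group = group, groups = groups,
    n = vapply(an, length, 0L), n_clusters = n_cl, m = m,
    window_multi_fraction = f_nb,
    region = yields$region[1], wavenumber = wavenumber,
    n_rep = n_rep, keep_frac = keep_frac, method = method, seed = seed),
    class = "yield_boot")
}

#' Confidence interval for a bootstrapped composite
#'
#' `type = "subsampling"` (default) rescales the replicate deviations by
#' `sqrt(m/(n-m))` per group -- the m-out-of-n subsampling calibration,
#' for which `(1/m - 1/n) * m/(n-m) = 1/n` exactly -- so the interval
#' reflects full-sample uncertainty.  `type = "percentile"` returns the
#' raw replicate quantiles (the descriptive box-whisker spread of the
#' subsampled composites).
#'
#' @param object a [bootstrap_composite()] result.
#' @param parm unused.
#' @param level confidence level.
#' @param type `"subsampling"` or `"percentile"`.
#' @param ... unused.
#' @return length-2 numeric (lower, upper).
#' @export
confint.yield_boot <- function(object, parm, level = 0.95,
                               type = c("subsampling", "percentile"), ...) {
  type <- match.arg(type)
  a <- (1 - level) / 2
  if (type == "percentile")
    return(stats::quantile(object$replicates, c(a, 1 - a), names = FALSE))
  scale2 <- object$m / (object$n_clusters - object$m)
  v <- sum(apply(object$group_replicates, 2, stats::var) * scale2)
  tq <- stats::qt(1 - a, df = min(object$n_clusters) - 1L)
  ci <- stats::median(object$raw_replicates) + c(-1, 1) * tq * sqrt(v)
  if (object$group == "contrast" && is.finite(object$window_multi_fraction)) {
    cf <- ci / 100
    ci <- 100 * cf / (1 - cf * object$window_multi_fraction)
  }
  ci
}

#' @export
print.yield_boot <- function(x, ...) {
  ci <- confint(x)
  cat(sprintf(
    "<yield_boot> %s, k=%d, %s composite: %.2f%% (95%% CI %.2f..%.2f), n=%s, %d reps\n",
    x$region, x$wavenumber, x$group, x$point, ci[1], ci[2],
    paste(x$n, collapse = "/"), x$n_rep))
  invisible(x)
}

#' @export
plot.yield_boot <- function(x, ...) {
  graphics::boxplot(x$replicates,
                    ylab = "composite yield anomaly (%)",
                    main = sprintf("%s, wave-%d, %s", x$region,
                                   x$wavenumber, x$group), ...)
  invisible(x)
}
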