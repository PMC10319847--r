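#' Classify regional years as below- or above-trend
#'
#' A year is "low" for a region when its trend-relative yield anomaly is
#' strictly negative ("below the multiyear trend"), "high" when positive.
#' An exactly zero anomaly is classified per `zero_as` (default `"high"`,
#' since "below" is strict); ties vanish with float data.
#'
#' @param anomalies data frame (region, year, anomaly) of fractional
#'   trend-relative anomalies (e.g. from [ssa_detrend()]).
#' @param zero_as `"high"` or `"low"`.
#' @return An object of class `sign_table`: logical years x regions matrix
#'   `TRUE` = low, with the year vector as rownames.
#' @export
classify_years <- function(anomalies, zero_as = c("high", "low")) {
  zero_as <- match.arg(zero_as)
  stopifnot(all(c("region", "year", "anomaly") %in% names(anomalies)))
  regions <- unique(anomalies$region)
  years <- sort(unique(anomalies$year))
  low <- matrix(NA, length(years), length(regions),
                dimnames = list(years, regions))
  idx <- cbind(match(anomalies$year, years),
               match(anomalies$region, regions))
  low[idx] <- if (zero_as == "high") anomalies$anomaly < 0
              else anomalies$anomaly <= 0
  structure(low, zero_as = zero_as, class = "sign_table")
}

#' Likelihood multiplication factor from contingency counts
#'
#' The LMF is the ratio of two conditional hit rates of concurrent
#' same-sign yields in a region pair: `p_event = N_joint_event / N_event`
#' among multi-event summers over `p_noevent = N_joint_noevent /
#' N_noevent` among zero-event summers.  An LMF above one means wave
#' events multiply the likelihood of concurrent lows (or highs); when the
#' no-event hit rate is zero the LMF is undefined and reported as NA
#' rather than infinity.
#'
#' @param n_joint_event concurrent-hit years among multi-event years.
#' @param n_event number of multi-event years.
#' @param n_joint_noevent concurrent-hit years among zero-event years.
#' @param n_noevent number of zero-event years.
#' @param pair,wavenumber,mode optional metadata carried into the result.
#' @return An object of class `lmf`: counts, hit rates, `lmf`, metadata.
#' @export
lmf_counts <- function(n_joint_event, n_event, n_joint_noevent, n_noevent,
                       pair = c(NA, NA), wavenumber = NA, mode = "low") {
  counts <- c(n_joint_event, n_event, n_joint_noevent, n_noevent)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_event <= 0 || n_noevent <= 0)
    stop("empty conditioning set: need N_event > 0 and N_noevent > 0")
  if (n_joint_event > n_event || n_joint_noevent > n_noevent)
    stop("joint counts cannot exceed their conditioning totals")
  p1 <- n_joint_event / n_event
  p0 <- n_joint_noevent / n_noevent
  structure(list(
    pair = pair, wavenumber = wavenumber, mode = mode,
    n_joint_event = n_joint_event, n_event = n_event,
    n_joint_noevent = n_joint_noevent, n_noevent = n_noevent,
    p_event = p1, p_noevent = p0,
    lmf = if (p0 == 0) NA_real_ else p1 / p0,
    p_value = NA_real_),
    class = "lmf")
}

#' @export
print.lmf <- function(x, ...) {
  cat(sprintf("<lmf> %s x %s, wave-%s, %s: LMF = %s\n",
              x$pair[1], x$pair[2], x$wavenumber, x$mode,
              if (is.na(x$lmf)) "undefined (p_noevent = 0)"
              else sprintf("%.3f", x$lmf)))
  cat(sprintf("  p_event = %d/%d = %.3f, p_noevent = %d/%d = %.3f",
              x$n_joint_event, x$n_event, x$p_event,
              x$n_joint_noevent, x$n_noevent, x$p_noevent))
  if (!is.na(x$p_value)) cat(sprintf(", perm. p = %.4f", x$p_value))
  cat("\n")
  invisible(x)
}

# Internal: concurrent-hit indicator for a pair, given the sign table.
joint_hits <- function(signs, pair, mode) {
  l1 <- signs[, pair[1]]
  l2 <- signs[, pair[2]]
  if (mode == "low") l1 & l2 else (!l1) & (!l2)
}

#' Likelihood multiplication factor for a region pair
#'
#' Counts concurrent low (or high) yield years within the multi-event and
#' zero-event summers of the calendar (single-event summers are excluded
#' from both conditioning sets) and forms the LMF.  Years missing from
#' either region's sign table are dropped pairwise.
#'
#' @param signs a [classify_years()] sign table.
#' @param calendar an [event_calendar()].
#' @param pair character vector of two region names.
#' @param wavenumber wavenumber whose calendar is used.
#' @param mode `"low"` or `"high"`.
#' @return An `lmf` object (see [lmf_counts()]).
#' @export
lmf <- function(signs, calendar, pair, wavenumber,
                mode = c("low", "high")) {
  mode <- match.arg(mode)
  stopifnot(inherits(signs, "sign_table"), length(pair) == 2L,
            all(pair %in% colnames(signs)))
  years <- as.integer(rownames(signs))
  hit <- joint_hits(signs, pair, mode)
  ok <- !is.na(hit)
  ev_years <- calendar_years(calendar, wavenumber, "multi")
  z_years <- calendar_years(calendar, wavenumber, "zero")
  in_ev <- ok & years %in% ev_years
  in_z <- ok & years %in% z_years
  if (!any(in_ev) || !any(in_z))
    stop(sprintf("pair %s-%s, wave-%d: empty conditioning set",
                 pair[1], pair[2], wavenumber))
  lmf_counts(sum(hit[in_ev]), sum(in_ev), sum(hit[in_z]), sum(in_z),
             pair = pair, wavenumber = wavenumber, mode = mode)
}

#' Pairwise LMF grid over all region pairs
#'
#' Computes the LMF for every unordered region pair, for concurrent lows
#' and concurrent highs.  Per-pair failures (e.g. an empty conditioning
#' set) yield NA rows instead of aborting the grid.  [as.matrix()] lays
#' the values out heatmap-style with concurrent lows in the upper-right
#' triangle and concurrent highs in the lower-left.
#'
#' @param signs a [classify_years()] sign table.
#' @param calendar an [event_calendar()].
#' @param wavenumber wavenumber whose calendar is used.
#' @param mode `"both"` (default), `"low"` or `"high"`.
#' @return An object of class `lmf_matrix`: data frame region_a,
#'   region_b, mode, counts, hit rates, lmf.
#' @export
lmf_matrix <- function(signs, calendar, wavenumber,
                       mode = c("both", "low", "high")) {
  mode <- match.arg(mode)
  regions <- colnames(signs)
  if (length(regions) < 2L) stop("need at least 2 regions")
  modes <- if (mode == "both") c("low", "high") else mode
  pairs <- utils::combn(regions, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) do.call(rbind, lapply(modes, function(m) {
    r <- tryCatch(lmf(signs, calendar, p, wavenumber, m),
                  error = function(e) NULL)
    if (is.null(r))
      data.frame(region_a = p[1], region_b = p[2], wavenumber = wavenumber,
                 mode = m, n_joint_event = NA, n_event = NA,
                 n_joint_noevent = NA, n_noevent = NA,
                 p_event = NA, p_noevent = NA, lmf = NA_real_)
    else
      data.frame(region_a = p[1], region_b = p[2], wavenumber = wavenumber,
                 mode = m, n_joint_event = r$n_joint_event,
                 n_event = r$n_event, n_joint_noevent = r$n_joint_noevent,
                 n_noevent = r$n_noevent, p_event = r$p_event,
                 p_noevent = r$p_noevent, lmf = r$lmf)
  })))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "regions") <- regions
  class(out) <- c("lmf_matrix", "data.frame")
  out
}

#' @export
as.matrix.lmf_matrix <- function(x, ...) {
  regions <- attr(x, "regions")
  M <- matrix(NA_real_, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (i in seq_len(nrow(x))) {
    a <- match(x$region_a[i], regions)
    b <- match(x$region_b[i], regions)
    if (x$mode[i] == "low") M[min(a, b), max(a, b)] <- x$lmf[i]
    else M[max(a, b), min(a, b)] <- x$lmf[i]
  }
  M
}

#' Permutation test for the low-versus-high LMF asymmetry
#'
#' Tests whether wave events modulate concurrent lows and concurrent
#' highs differently, via the statistic `LMF_low - LMF_high`.  The null is
#' built by shuffling the calendar's year classes across years (preserving
#' the multi/single/zero class counts) and recomputing the statistic; the
#' two-sided p-value uses the add-one correction.  If the statistic is
#' undefined in more than half of the permutations the p-value is
#' reported as NA.
#'
#' @param signs a [classify_years()] sign table.
#' @param calendar an [event_calendar()].
#' @param pair two region names.
#' @param wavenumber wavenumber whose calendar is used.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional seed, recorded in the result.
#' @return list with `statistic` (observed LMF_low - LMF_high),
#'   `p_value`, `n_perm`, `n_undefined`, `seed`.
#' @export
lmf_significance <- function(signs, calendar, pair, wavenumber,
                             n_perm = 1000L, seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  years <- as.integer(rownames(signs))
  cal <- calendar[calendar$wavenumber == wavenumber, ]
  cls <- cal$class[match(years, cal$year)]
  if (anyNA(cls)) stop("calendar does not cover all sign-table years")
  hit_low <- joint_hits(signs, pair, "low")
  hit_high <- joint_hits(signs, pair, "high")
  ok <- !is.na(hit_low)
  stat <- function(classes) {
    ev <- ok & classes == "multi"
    z <- ok & classes == "zero"
    ne <- sum(ev); nz <- sum(z)
    if (ne == 0 || nz == 0) return(NA_real_)
    p0l <- sum(hit_low[z]) / nz
    p0h <- sum(hit_high[z]) / nz
    if (p0l == 0 || p0h == 0) return(NA_real_)
    (sum(hit_low[ev]) / ne) / p0l - (sum(hit_high[ev]) / ne) / p0h
  }
  obs <- stat(cls)
  if (is.na(obs))
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_perm = n_perm, n_undefined = NA_integer_, seed = seed))
  null <- vapply(seq_len(n_perm), function(b) stat(sample(cls)), 0.0)
  n_undef <- sum(is.na(null))
  p <- if (n_undef > n_perm / 2) NA_real_
       else (1 + sum(abs(null) >= abs(obs), na.rm = TRUE)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_perm = n_perm,
       n_undefined = n_undef, seed = seed)
}

#' Cross-model agreement on the side of LMF = 1
#'
#' Fraction of models whose LMF falls on the same side of one as the
#' multi-model mean; agreement of at least 3/4 earns one dot, unanimity
#' two dots (the heatmap annotation convention).  Undefined LMFs are
#' excluded from the count and noted.
#'
#' @param values numeric LMFs, one per model (>= 2 non-missing).
#' @return list with `fraction`, `side` (`"above"`/`"below"`), `dots`
#'   (0, 1 or 2), `n_models`, `n_undefined`.
#' @export
model_agreement <- function(values) {
  n_undef <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("need at least 2 models with defined LMF")
  side_up <- mean(v) > 1
  agree <- if (side_up) v > 1 else v < 1
  frac <- mean(agree)
  dots <- if (frac == 1) 2L else if (frac >= 0.75) 1L else 0L
  list(fraction = frac, side = if (side_up) "above" else "below",
       dots = dots, n_models = length(v), n_undefined = n_undef)
}
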