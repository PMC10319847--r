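#' Generate multi-region annual yield tables with planted event effects
#'
#' Per region, annual yield follows a smooth technology trend multiplied by
#' `(1 - event_effect)` in multi-event summers of the driver wavenumber and
#' by a lognormal shock `exp(eps)`.  In multi-event years the shocks of the
#' regions are correlated with coefficient `concurrence`; in all other
#' years they are independent.  Production is yield times a fixed harvested
#' area, mirroring national statistics tables (region, year, production,
#' area).
#'
#' The ground truth records, in closed form from the generative conditional
#' probabilities, the pairwise likelihood multiplication factor implied by
#' the design, and the composite yield effects implied for the
#' multi-event and zero-event groups under the +-3-year neighbor
#' standardization (which are contaminated by event effects in the
#' neighbor windows; their difference equals the planted `-100 *
#' event_effect` to first order).
#'
#' @param config a [sim_config()] with `event_effect` in \[0, 1).
#' @param truth a `wave_truth` from [gen_wave_spectrum()] or
#'   [gen_wind_field()], providing the event calendar.
#' @return An object of class `yield_sim`: list with `yields` (data frame
#'   region, year, production, area, yield) and `truth` (multi/zero year
#'   sets, implied composites and implied LMF).
#' @export
gen_yield_series <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "wave_truth"))
  if (config$event_effect < 0 || config$event_effect >= 1)
    stop("event_effect must lie in [0, 1)")
  set.seed(config$seed + 2L)
  ny <- config$years
  regions <- config$regions
  nr <- length(regions)
  e <- config$event_effect
  rho <- config$concurrence
  sig <- config$noise_sd$yield

  ev <- truth$events
  ev <- ev[ev$wavenumber == config$driver_wavenumber, , drop = FALSE]
  counts <- tabulate(ev$year, nbins = ny)
  multi <- counts >= 2L
  zero <- counts == 0L

  eps <- matrix(stats::rnorm(ny * nr, sd = sig), ny, nr)
  if (rho != 0 && any(multi) && sig > 0) {
    S <- matrix(rho * sig^2, nr, nr)
    diag(S) <- sig^2
    L <- chol(S)
    eps[multi, ] <- matrix(stats::rnorm(sum(multi) * nr), sum(multi), nr) %*% L
  }

  yr <- seq_len(ny)
  yields <- do.call(rbind, lapply(seq_len(nr), function(r) {
    tr <- config$yield_trend[[r]]
    trend <- tr[1] + tr[2] * (yr - 1)
    if (any(trend <= 0)) stop("yield trend must stay positive")
    y <- trend * (1 - e * multi) * exp(eps[, r])
    data.frame(region = regions[r], year = yr,
               production = y * config$area_ha[r],
               area = config$area_ha[r], yield = y)
  }))
  rownames(yields) <- NULL

  # implied per-group composites under +-3-year neighbor standardization
  frac_multi_nb <- function(y) {
    nb <- setdiff(max(1, y - 3):min(ny, y + 3), y)
    mean(multi[nb])
  }
  imp_event <- if (any(multi))
    mean(vapply(which(multi), function(y)
      100 * ((1 - e) / (1 - e * frac_multi_nb(y)) - 1), 0.0)) else NA_real_
  imp_control <- if (any(zero))
    mean(vapply(which(zero), function(y)
      100 * (1 / (1 - e * frac_multi_nb(y)) - 1), 0.0)) else NA_real_

  # implied LMF (classification against the true trend, closed form)
  if (sig > 0) {
    thr <- -log(1 - e) / sig
    cor2 <- matrix(c(1, rho, rho, 1), 2, 2)
    p_joint_low_ev <- mvtnorm::pmvnorm(upper = c(thr, thr), corr = cor2)[1]
    p_joint_high_ev <- mvtnorm::pmvnorm(lower = c(thr, thr), corr = cor2)[1]
    implied_lmf_low <- p_joint_low_ev / 0.25
    implied_lmf_high <- p_joint_high_ev / 0.25
  } else {
    implied_lmf_low <- implied_lmf_high <- NA_real_
  }

  structure(
    list(yields = yields,
         truth = list(
           multi_years = which(multi), zero_years = which(zero),
           event_counts = counts,
           implied_event_composite = imp_event,
           implied_control_composite = imp_control,
           implied_contrast = if (is.na(imp_event) || is.na(imp_control))
             NA_real_ else imp_event - imp_control,
           implied_lmf_low = implied_lmf_low,
           implied_lmf_high = implied_lmf_high)),
    class = "yield_sim")
}
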