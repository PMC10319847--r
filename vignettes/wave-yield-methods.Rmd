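---
title: "Methods: Rossby wave events, yield composites, and the likelihood multiplication factor"
author: "waveyield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rossby wave events, yield composites, and the LMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures the package
implements, the assumptions behind them, the tunable parameters with
their defaults, and the design choices made where the methodology left
genuine freedom. It states no empirical result that the test suite and
the acceptance script do not themselves compute.

## 1. Wave diagnostics and event definition

The object of analysis is the June–August (JJA) 250 mb meridional wind.
Each 92-day season (day 1 = June 1, non-leap calendar) is reduced to

1. a daily zonal profile: the cosine-latitude-weighted mean over the
   mid-latitude band 37.5–57.5°N (`meridional_mean()`; the weighting is
   the standard area weighting for zonal-band means);
2. 13 weekly profiles: consecutive non-overlapping 7-day block means
   over days 1–91 (`weekly_average()`). Day 92 belongs to no block and
   is dropped — 13 × 7 = 91 and the single leftover day cannot form a
   week. Weekly averaging acts as an anti-aliasing low-pass filter on
   sub-weekly transients. Each week carries a center day (day 4 of its
   block) used later for event-centered surface windows;
3. standing-wave amplitudes and phases per zonal wavenumber
   (`fourier_decompose()`), with the convention that a profile
   `A cos(kλ − φ)` returns amplitude exactly `A` at wavenumber `k`.
   `k_max` defaults to 10; wavenumbers 5 and 7 are the teleconnection
   patterns of interest. Amplitude recovery is exact to float tolerance
   and Parseval's identity is asserted in the tests.

A **wave event** is a week whose amplitude strictly exceeds the
wavenumber's JJA climatological mean by more than `threshold_sd` = 1.5
standard deviations (`detect_events()`). Choices made here:

* the climatology (`build_climatology()`) uses the sample (n−1) standard
  deviation, configurable to the population estimator;
* "exceeds" is strict (`>`); a tolerance of `1e-8·(mean + sd)` guards
  against float jitter registering as upward-broken ties on numerically
  constant records;
* consecutive exceedance weeks count as separate events; no merging of
  persistent episodes is attempted;
* several wavenumbers exceeding in the same week yield one event each —
  waves are analyzed separately throughout.

Summers are classed per wavenumber as **multi-event** (≥ 2 events,
`multi_min` configurable), **zero-event**, or **single-event**; the last
class enters neither the composites nor the LMF conditioning sets, so
the contrast is between clearly wave-active and wave-quiet summers.

## 2. Surface anomalies and composites

`detrend_field()` removes, per grid point, an OLS linear trend against
the **year index** and then the day-in-season climatological mean of the
detrended data. Regressing on the year index rather than the day index
keeps a purely repeating seasonal cycle from leaking into the trend
estimate (the two are exactly orthogonal), and the subsequent
climatology removal makes the day-of-season mean of the anomalies
exactly zero over the reference period — both properties are asserted
in the tests.

Event-centered weekly anomalies (`weekly_anomaly()`) are 7-day windows
centered on the event's center day: means for temperature and wind,
7-day aggregates for precipitation. Windows truncated by the season
edge shrink to the available days and are flagged, rather than dropping
the event, so sample sizes stay matched to event counts.

`composite_map()` averages these maps over all events of a wavenumber.
Significance hatching is by Monte-Carlo resampling: `n_mc` (default
1000) composites of equally many randomly drawn non-event weeks form a
null distribution per grid point, and the observed composite is flagged
where it falls outside the central 95% of that null (two-sided). This
respects the compositing structure; the test is per grid point with no
multiplicity control, and its type-I rate is checked on null synthetic
data. `pattern_correlation()` compares two composite maps over the
38–58°N belt with cos-latitude weights: Pearson r, and the
field-versus-field coefficient of determination
`R² = 1 − Σw(a−b)² / Σw(a−ā)²` with the *first* argument as reference —
this R² is order-dependent and may be negative; the asymmetry is
deliberate and documented. `flux_to_depth()` converts model
precipitation flux (kg m⁻² s⁻¹) to depth per hour by the exact factor
3.6.

## 3. Yield pipeline

Regional yields are total production over total harvested area, pooling
member countries and crops (wheat+maize pooled *before* any detrending;
`aggregate_region()`). Trends are removed with singular spectrum
analysis (`ssa_detrend()`): embedding window `L = 10` years, so
anomalies measure variability relative to roughly 10-year moving
windows; eigentriples whose reconstructed components carry at least
`low_freq_share` = 0.75 of their spectral power at periods longer than
`L` form the trend. Series shorter than `2L` fall back to a flagged
LOESS local-linear trend of comparable bandwidth. The SSA specifics
(embedding length, component selection) are necessarily a concrete
choice among many defensible ones; both knobs are exposed.

For composites, each group year is standardized by the mean yield of
the three years preceding and following it (`normalize_event_yield()`),
expressing it as a fraction of contemporaneous production; boundary
years keep a shrunken window but need at least 3 neighbor years with at
least one on each side, otherwise they are excluded and flagged. The
SSA-trend-relative anomalies are used for *sign classification* (LMF),
the ±3-year standardization for *composites*; a switch
(`method = "ssa"`) exposes the alternative.

### Why the event-minus-control contrast

Whenever a substantial fraction *f* of summers is multi-event, the
±3-year neighborhood of an event year contains other event years, so
the raw multi-event composite converges to `−e(1−f)` rather than the
planted loss `−e` — at *f* ≈ 0.26 (the observation-like event rate) a
5% loss appears as ≈ −3.7%. The same contamination holds for any
trend-relative anomaly, including SSA. The zero-event (control)
composite is biased by exactly the complementary amount `+ef`, so the
**contrast** (multi-event minus control) recovers `−e` to first order.
`bootstrap_composite(group = "contrast")` therefore reports the
contrast, with a plug-in second-order correction that inverts
`c = −e/(1 − e·f̂)` using the observable multi-event fraction `f̂`
inside the standardization windows. The generator's ground truth
records both the contaminated per-group values implied by the realized
calendar and the contrast, and parameter recovery is tested against the
planted effect.

### Bootstrap uncertainty

Uncertainty comes from 500 replicates, each re-estimating the composite
from a ~90% subsample drawn **without replacement**; the replicate
median is the reported point estimate and the replicate quantiles are
the descriptive box-whisker spread. Two consequences are handled
explicitly:

* *Scale.* m-out-of-n subsampling deviations are smaller than
  full-sample sampling error; `confint()` rescales them by
  `sqrt(m/(n−m))`, for which `(1/m − 1/n)·m/(n−m) = 1/n` exactly, so
  the default interval reflects full-sample uncertainty (Student-t
  quantiles with block-count degrees of freedom). The raw percentile
  interval remains available as `type = "percentile"`.
* *Serial dependence.* Standardization windows of group years closer
  than 7 years overlap, positively correlating their anomalies; the
  resampling unit is therefore the contiguous 7-year calendar block
  (the window diameter), not the single year — the standard block
  adaptation. At least one block is always left out so replicates have
  spread.

With these two corrections the nominal 95% interval attains ≈ 95%
coverage of a planted effect in simulation; with year-wise resampling
and raw percentile intervals the coverage would be far below nominal
(the raw subsample spread is about one third of a standard error).

## 4. The likelihood multiplication factor

For a region pair, a year is *low* when its trend-relative anomaly is
strictly negative ("below the multiyear trend"); an exactly zero
anomaly counts as *high* by default (`zero_as`), consistent with the
strict reading — ties vanish with float data. The LMF is the ratio of
the concurrent-low hit rate among multi-event years to that among
zero-event years (`lmf()`, `lmf_counts()`); concurrent highs are
treated symmetrically. `p_noevent = 0` makes the LMF undefined; it is
reported as missing, not infinity, so heatmaps and agreement statistics
stay finite. The implementation is verified against exhaustive
contingency counting on random calendars.

The low-vs-high asymmetry test (`lmf_significance()`) permutes the
calendar's year classes (preserving class counts) and recomputes
`LMF_low − LMF_high`, with a two-sided add-one p-value; if more than
half the permutations leave the statistic undefined the p-value is
reported as unavailable. The exact construction used in the original
analyses of this kind is not recoverable from their main text; the
label permutation is a documented stand-in that is exact under
exchangeability. `model_agreement()` scores the fraction of models on
the same side of LMF = 1 as the multi-model mean (≥ 3/4 one dot,
unanimity two dots).

## 5. The synthetic generator

The generator is a validation instrument, not an atmosphere model. It
emulates exactly the features the pipeline consumes:

* **Wind**: weekly standing waves `A_k cos(kλ − φ_k)`, uniform across
  latitude, phase re-drawn per week and frozen within it
  (quasi-stationarity). Background weekly amplitudes are
  truncated-normal (`base_amplitude_mean` 2.0, SD 0.8 m/s); planted
  event weeks (Bernoulli per week, `event_rate` = 1 expected exceedance
  week per season, the observation-like rate) are set to
  `base_amplitude_mean + 3·SD + 1` m/s. The ground truth records as
  events exactly the weeks whose generated amplitude exceeds the
  empirical mean by > 1.5 sample SD — the detector's own rule — so on
  noise-free fields detected and true events coincide identically, a
  property asserted over 100 seeds.
* **Surface**: warm anomalies a quarter wavelength downstream of the
  southerly wind maximum (ridges), `coupling_temp` = 1 K per m/s, on
  top of a smooth within-season cycle and optional linear warming;
  precipitation is suppressed under ridges (`coupling_precip` = 0.05
  per m/s) around 2.5 mm/day and clipped at zero.
* **Yields**: per region, yield = linear technology trend
  (3 t/ha + 0.03 t/ha/yr) × `(1 − event_effect·1[multi-event year])` ×
  `exp(ε)`, lognormal so yields stay positive, `event_effect` = 0.05,
  shock SD 5%/yr, with correlation `concurrence` = 0.3 across regions
  in multi-event years and independence otherwise. Five regions mirror
  the NA/WEU/EEU/IND/EAS breadbasket set. The implied pairwise LMF is
  computed in closed form from bivariate-normal orthant probabilities
  and cross-checked by direct counting.

What the generator does **not** emulate — dynamical wave propagation,
land/ocean contrast, crop phenology, harvested-area dynamics, bias
adjustment — bounds what passing tests show: they validate the
statistical machinery (estimators, calibration, determinism), not the
fidelity of any real-world dataset. All distributional choices are
stand-ins, made once and documented here.

## 6. Numerical choices, problem sizes, degenerate inputs

* Coordinates: latitudes ascending, longitudes [0, 360), uniform grids;
  the Fourier step refuses non-uniform or non-periodic grids; `k_max`
  is capped at n_lon/2 with the Nyquist amplitude handled specially.
* The wind grid must span the full 37.5–57.5°N band; narrower grids are
  refused with the missing range named.
* Every stochastic stage takes an explicit seed; `sim_config()` refuses
  to build without one, and `run_pipeline()` writes all derived seeds
  into its manifest. Identical configs reproduce identical outputs
  bit-exactly (asserted on file hashes).
* Calibration tests run at deliberately moderate sizes — 200-year
  records, 50 seeds for the null calibration, 20 for effect recovery,
  100 for the detection oracle, coarse (5°) grids for field-level
  checks — sizes at which the asserted tolerances are comfortably
  identifiable in simulation.
* Degenerate inputs are defined errors: empty composite groups and
  empty LMF conditioning sets name the offending region/wavenumber;
  zero-variance reference fields refuse a pattern correlation;
  non-positive SSA trends abort rather than produce meaningless
  fractional anomalies.

## 7. Known limitations

* The permutation test's add-one p-value is mildly conservative under
  heavy ties (small records); uniformity is verified at 200-year scale.
* The plug-in contamination correction is first-order in the event
  effect; for losses far beyond ~10% the contrast would need the exact
  inversion per group.
* Pattern-correlation significance is not implemented (the belt metric
  is descriptive, as in the analyses it mirrors).
* The pipeline accepts a second period (e.g. a future scenario) by
  re-running on that period's data; no scenario interpretation is
  built in.
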