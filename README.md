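# waveyield

Amplified quasi-stationary Rossby waves — zonal wavenumber-5 and
wavenumber-7 meanders of the boreal summer jet — phase-lock heat and
drought anomalies over several northern-hemisphere breadbaskets at once.
`waveyield` implements the full analysis chain that links such wave events
to regional and *concurrent* crop-yield anomalies, for climate-impact and
food-security researchers who want the machinery as tested, reusable R
functions rather than one-off scripts:

1. **Wave diagnostics** — cosine-latitude-weighted meridional mean of the
   250 mb meridional wind over 37.5–57.5°N, weekly (7-day block) averages
   of the 92-day June–August season, fast Fourier decomposition into
   standing waves `A_k cos(kλ − φ_k)`, and detection of **wave events**:
   weeks whose amplitude exceeds the wavenumber's JJA climatological mean
   by more than 1.5 standard deviations.  Summers are classed
   *multi-event* (≥ 2 events), *zero-event*, or *single-event*
   (excluded from all composites).
2. **Surface anomalies** — per-gridpoint linear detrending plus
   day-in-season climatology removal, event-centered weekly anomaly
   composites (mean for temperature/wind, 7-day aggregate for
   precipitation) with Monte-Carlo significance, belt pattern correlation
   (Pearson r and the field-vs-field R², which unlike a regression R² may
   be negative), and harvested-area-masked regional anomaly
   distributions.
3. **Yield pipeline** — FAO-style regional aggregation
   (Σ production / Σ area, pooling countries and crops), singular
   spectrum analysis (SSA) detrending against ~10-year windows,
   ±3-year neighbor standardization of event years, and composite yield
   anomalies for multi-event vs zero-event summers with a 500-replicate
   ~90% subsample bootstrap.
4. **Concurrence** — the **likelihood multiplication factor**

   LMF = p_event / p_noevent,  p_event = N(both low ∧ multi-event) / N(multi-event),
   p_noevent = N(both low ∧ zero-event) / N(zero-event),

   i.e. the factor by which wave events multiply the probability that a
   *pair* of regions is below trend in the same year (analogously for
   concurrent highs), with a label-permutation test of the low-vs-high
   asymmetry and cross-model agreement scoring.
5. **Synthetic generator** — reanalysis-like wind/temperature/precipitation
   fields with planted events, phase-locked surface coupling, and
   multi-region yield tables with technology trends, event-year losses and
   cross-region shock concurrence — so every stage can be validated
   against a known ground truth.

## Worked example

A 55-summer synthetic record at the default, observation-like operating
point (≈ 1 exceedance week per season and wavenumber, 5 breadbasket
regions, 5% yield loss in multi-event years):

```r
library(waveyield)

cfg <- sim_config(years = 55, grid_step = 2.5, seed = 42)
w   <- gen_wind_field(cfg)
sp  <- fourier_decompose(weekly_average(meridional_mean(w$field)), k_max = 8)
ev  <- detect_events(sp, build_climatology(sp), wavenumbers = c(5, 7))
cal <- event_calendar(ev, c(1, 55), c(5, 7))
summary(cal)
#>   wavenumber n_events multi_years single_years zero_years
#> 1          5       55          15           18         22
#> 2          7       79          25           20         10
```

55 wave-5 events in 55 summers, with 15 multi-event and 22 zero-event
years — the same order as observational records.  The composite yield
effect of multi-event summers, as the multi-event-minus-control contrast
(see the methods vignette for why the contrast, not the raw group
composite, recovers the planted effect):

```r
ys <- gen_yield_series(cfg, w$truth)
bootstrap_composite(ys$yields, cal, 5, "contrast", region = "NAM", seed = 43)
#> <yield_boot> NAM, k=5, contrast composite: -7.46% (95% CI -12.61..-2.14), n=14/21, 500 reps
```

Multi-event summers cost the NAM region about 7% of contemporaneous
production relative to event-free summers (the planted truth is −5%,
well inside the interval).  Concurrence across regions:

```r
an <- do.call(rbind, lapply(split(ys$yields, ys$yields$region), function(d)
  data.frame(region = d$region[1], year = d$year,
             anomaly = ssa_detrend(d$yield)$anomaly)))
signs <- classify_years(an)
lmf(signs, cal, c("NAM", "WEU"), 5, "low")
#> <lmf> NAM x WEU, wave-5, low: LMF = 2.933
#>   p_event = 8/15 = 0.533, p_noevent = 4/22 = 0.182
lmf_significance(signs, cal, c("NAM", "WEU"), 5, n_perm = 999, seed = 44)$p_value
#> 0.049
```

Concurrent NAM×WEU low-yield years are 2.9 times more likely in
multi-event than in zero-event summers (planted concurrence 0.3), and the
low-vs-high asymmetry is significant at the 5% level.
`as.matrix(lmf_matrix(signs, cal, 5))` lays all pairs out heatmap-style,
concurrent lows upper-right, concurrent highs lower-left.

`run_pipeline(cfg, "out/")` chains all stages, writing NetCDF fields, CSV
tables and a JSON manifest (config hash, seeds, per-year event counts);
re-running the same config reproduces every output bit-exactly.

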