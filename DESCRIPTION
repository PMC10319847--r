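Package: waveyield
Title: Quasi-Stationary Rossby Wave Events and Concurrent Crop Yield Anomalies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects high-amplitude quasi-stationary Rossby wave events
    (zonal wavenumbers 5 and 7) from gridded upper-level meridional winds,
    forms event-centered surface temperature and precipitation anomaly
    composites with Monte-Carlo significance, estimates regional composite
    crop-yield anomalies for multi-event versus zero-event summers with
    subsample-bootstrap uncertainty after singular-spectrum-analysis
    detrending, and quantifies concurrent low (or high) yields across
    region pairs with the likelihood multiplication factor (LMF) and a
    permutation test.  Ships a synthetic-data generator that emulates
    reanalysis-like wind, temperature and precipitation fields with
    planted wave events and multi-region annual yield tables with known
    trends, event effects and concurrence structure, so the whole chain
    can be validated against a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    mvtnorm,
    ncdf4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
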