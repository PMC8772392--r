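Package: urbanheat
Title: Urban Heat Island Intensity and Excess Heat Factor Analysis on
    Gridded Temperature Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating heat-related exposure from gridded hourly
    2-m temperature fields: urban heat island intensity (UHII) quantified as
    the slope of temperature regressed on urban fraction, Excess Heat Factor
    (EHF) risk mapping built from 3-day and 30-day mean temperatures against
    a multi-year 95th-percentile climatology baseline, day/night diurnal
    partitioning, daily Tmax/Tmin/Tmean statistics, urban-to-rural
    cross-sections, and station-based model-evaluation statistics (mean
    bias, gross error, RMSE). Includes a seeded synthetic gridded-meteorology
    generator (diurnal cycle, multi-day heatwave pulse with distinct
    urban/rural amplitudes, nighttime urban warming proportional to urban
    fraction, lake-breeze cooling, synoptic day-to-day variability and
    observation noise) so every estimator can be checked against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
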