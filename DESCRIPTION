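Package: nearroad
Title: Link-Based Mobile-Source Emissions and Near-Road Dispersion for
    Exposure Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A bottom-up pipeline for estimating near-road air-pollutant
    concentrations for exposure studies. Hourly link-based emissions are
    built from annual average daily traffic, temporal allocation factors,
    vehicle fleet mixes and speed/temperature-dependent emission-factor
    lookup tables, and combined with unit-emission Gaussian line-source
    dispersion driven by Monin-Obukhov surface meteorology. Includes
    receptor cohort classification (high-traffic high-diesel,
    high-traffic low-diesel, low-traffic), period exposure summaries with
    completeness rules, effective-distance decay profiles,
    measurement-driven traffic-volume and diesel-fraction adjustments,
    and seeded synthetic-scenario generators so the full methodology can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
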