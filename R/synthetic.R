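# Seeded generators for every pipeline input: a small urban network with a
# high-diesel interstate corridor and a low-diesel freeway corridor,
# participant receptors around both, a diurnal meteorology series cycling
# the four stability regimes, an emission-factor table with the
# diesel-marker / traffic-marker contrast, temporal allocation factors and
# traffic-recorder records.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic scenario specification
#'
#' All knobs of the synthetic generators with their default study
#' conditions: a toy network (two 12 km high-traffic corridors - one
#' high-diesel interstate, one low-diesel freeway - plus arterials and
#' locals), ~30 participants placed 25-290 m from the corridors on both
#' sides (plus a far low-traffic group), 90 days of hourly meteorology with
#' a pre-dawn-stable/midday-convective diurnal cycle and northwest
#' prevailing winds, and the three-pollutant emission-factor structure
#' (diesel marker, intermediate, traffic marker).
#'
#' @param ... named overrides of any default.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(...) {
  spec <- list(
    # network
    n_corridor_segments = 6L, segment_length = 2000,
    corridor_aadt_range = c(70000, 110000),
    corridor_speeds = c(offpeak1 = 60, ampeak = 45, midday = 55, pmpeak = 45),
    n_arterials = 6L, arterial_aadt_range = c(8000, 18000),
    arterial_speeds = c(offpeak1 = 28, ampeak = 22, midday = 26, pmpeak = 22),
    n_locals = 2L, local_aadt_range = c(1000, 5000), local_speed = 25,
    neighborhood_offset = 30000,  # m between the HD and LD neighborhoods
    # participants
    n_per_cohort = 10L,
    cohort_distances = c(25, 50, 75, 100, 125, 150, 200, 240, 270, 290),
    lt_distance_range = c(350, 800),
    # meteorology
    start = as.POSIXct("2010-08-01 00:00:00", tz = "UTC"),
    n_days = 90L,
    prevailing_wdir = 315, wdir_sd = 45,
    met_jitter = 0.15, calm_frac = 0.04, missing_frac = 0.02,
    # regime schedule by hour of day
    regime_by_hour = c(rep("stable", 5), rep("very stable", 4),
                       rep("convective", 8), rep("neutral", 5),
                       rep("stable", 2)),
    # emission factors (g/veh/mi at the speed-curve minimum)
    ef_levels = list(
      pm25_like = c(diesel = 0.3, gasoline = 0.01),
      nox_like = c(diesel = 2.0, gasoline = 0.2),
      co_like = c(diesel = 10, gasoline = 10)),
    # temporal allocation
    weekday_peaks = c(am = 7.5, pm = 17.5), weekend_peak = 16,
    # traffic recorders
    ptr_interstate_bias = 0.20, ptr_bias_sd = 0.05,
    ptr_diesel_shares = c(0.09, 0.05),
    seed = 4217L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(spec))
    if (length(bad)) stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
    spec[names(ov)] <- ov
  }
  stopifnot(length(spec$regime_by_hour) == 24L, spec$n_days >= 1L,
            spec$n_per_cohort > 0L, spec$n_corridor_segments > 0L)
  structure(spec, class = "scenario_spec")
}

seg_geom <- function(x0, y0, x1, y1) rbind(c(x0, y0), c(x1, y1))

#' Generate the synthetic road network
#'
#' Deterministic for a seed. Two structurally identical neighborhoods
#' separated east-west (crosswind to the prevailing flow, so neither sits
#' systematically downwind of the other): one around an interstate
#' corridor (NFC 11, high diesel) at y = 0 and one around a freeway
#' corridor (NFC 12, low diesel) translated by the neighborhood offset.
#' The corridors are split into segments sharing the same drawn AADT
#' values, so the two differ only in fleet mix; each neighborhood also
#' carries north-south arterials (NFC 14/16) and a short local street
#' (NFC 17) with identical layout and volumes.
#'
#' @param spec a `scenario_spec`.
#' @param seed overrides `spec$seed`.
#' @return A `road_links` object.
#' @export
make_network <- function(spec = scenario_spec(), seed = spec$seed) {
  with_seed(seed, {
    ns <- spec$n_corridor_segments
    len <- spec$segment_length
    off <- spec$neighborhood_offset
    aadt <- stats::runif(ns, spec$corridor_aadt_range[1], spec$corridor_aadt_range[2])
    sp <- spec$corridor_speeds
    rows <- list()
    for (k in seq_len(ns)) {
      x0 <- (k - 1) * len
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("I-%02d", k), nfc = 11L, aadt = aadt[k],
        speed_offpeak1 = sp[["offpeak1"]], speed_ampeak = sp[["ampeak"]],
        speed_midday = sp[["midday"]], speed_pmpeak = sp[["pmpeak"]],
        geometry = list(seg_geom(x0, 0, x0 + len, 0)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("F-%02d", k), nfc = 12L, aadt = aadt[k],
        speed_offpeak1 = sp[["offpeak1"]], speed_ampeak = sp[["ampeak"]],
        speed_midday = sp[["midday"]], speed_pmpeak = sp[["pmpeak"]],
        geometry = list(seg_geom(off + x0, 0, off + x0 + len, 0)))
    }
    na <- spec$n_arterials
    a_aadt <- stats::runif(na, spec$arterial_aadt_range[1], spec$arterial_aadt_range[2])
    asp <- spec$arterial_speeds
    a_speeds <- vapply(asp, function(v) v * stats::runif(1, 0.95, 1.05), numeric(1))
    for (k in seq_len(na)) {
      # arterial k lives north of the corridor in both neighborhoods
      x <- (2 * ((k - 1) %% (na / 2)) + 1) * 1500 + if (k > na / 2) off else 0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("A-%02d", k), nfc = if (k %% 2) 14L else 16L,
        aadt = a_aadt[if (k > na / 2) k - na / 2 else k],
        speed_offpeak1 = a_speeds[["offpeak1"]], speed_ampeak = a_speeds[["ampeak"]],
        speed_midday = a_speeds[["midday"]], speed_pmpeak = a_speeds[["pmpeak"]],
        geometry = list(seg_geom(x, 1500, x, 6500)))
    }
    nl <- spec$n_locals
    l_aadt <- stats::runif(nl, spec$local_aadt_range[1], spec$local_aadt_range[2])
    for (k in seq_len(nl)) {
      x0 <- 2400 + if (k %% 2 == 0) off else 0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("L-%02d", k), nfc = 17L, aadt = l_aadt[k],
        speed_offpeak1 = spec$local_speed, speed_ampeak = spec$local_speed,
        speed_midday = spec$local_speed, speed_pmpeak = spec$local_speed,
        geometry = list(seg_geom(x0, -2000, x0 + 800, -2000)))
    }
    road_links(dplyr::bind_rows(rows))
  })
}

#' Generate synthetic participant receptors
#'
#' Places `n_per_cohort` receptors around the high-diesel corridor and,
#' mirrored, around the low-diesel corridor at the specified perpendicular
#' distances (alternating sides of the road), plus a far low-traffic group
#' beyond the classification radius. Construction guarantees that
#' [classify_receptors()] on the same network reproduces the intended
#' cohorts.
#'
#' @param spec a `scenario_spec`.
#' @param links the network from [make_network()] (same spec).
#' @param seed overrides `spec$seed`.
#' @return A `receptors` object (unclassified labels).
#' @export
make_participants <- function(spec = scenario_spec(), links = make_network(spec),
                              seed = spec$seed) {
  with_seed(seed + 1L, {
    n <- spec$n_per_cohort
    d <- rep_len(spec$cohort_distances, n)
    off <- spec$neighborhood_offset
    xlen <- spec$n_corridor_segments * spec$segment_length
    xs <- seq(0.15 * xlen, 0.9 * xlen, length.out = n) + stats::runif(n, -150, 150)
    side <- rep_len(c(-1, 1), n)  # alternate south/north of the road
    hd <- tibble::tibble(id = sprintf("P-HD-%02d", seq_len(n)),
                         x = xs, y = side * d)
    ld <- tibble::tibble(id = sprintf("P-LD-%02d", seq_len(n)),
                         x = off + xs, y = side * d)
    # low-traffic group: north of the corridors near the arterial band,
    # well beyond the classification radius, split across neighborhoods
    dlt <- stats::runif(n, spec$lt_distance_range[1], spec$lt_distance_range[2])
    lt <- tibble::tibble(id = sprintf("P-LT-%02d", seq_len(n)),
                         x = seq(0.1 * xlen, 0.95 * xlen, length.out = n) + 180 +
                           ifelse(seq_len(n) %% 2 == 0, off, 0),
                         y = 2500 + dlt)
    receptors(dplyr::bind_rows(hd, ld, lt))
  })
}

#' Generate synthetic hourly meteorology
#'
#' Cycles a diurnal stability pattern (stable pre-dawn, very stable through
#' the morning rush, convective midday, neutral evening), jittering the
#' surface parameters multiplicatively around the four representative
#' regime rows of [stability_regimes()] (jitter 0 reproduces them
#' verbatim). Wind directions concentrate around the prevailing northwest;
#' a configurable fraction of hours are calm (u < 0.5 m/s) and a fraction
#' have a missing Monin-Obukhov length (incomplete record).
#'
#' @param spec a `scenario_spec`.
#' @param seed overrides `spec$seed`.
#' @param n_days overrides `spec$n_days`.
#' @return A `met_hours` series of `24 * n_days` rows.
#' @export
make_met_series <- function(spec = scenario_spec(), seed = spec$seed,
                            n_days = spec$n_days) {
  with_seed(seed + 2L, {
    n <- 24L * n_days
    ts <- spec$start + 3600 * (seq_len(n) - 1L)
    hod <- as.POSIXlt(ts, tz = "UTC")$hour
    regime <- spec$regime_by_hour[hod + 1L]
    rg <- stability_regimes()
    ri <- match(regime, rg$regime)
    j <- function(v) v * exp(stats::rnorm(n, 0, spec$met_jitter))
    ustar <- j(rg$ustar[ri])
    zic <- j(rg$zic[ri])
    zim <- j(rg$zim[ri])
    L <- sign(rg$L[ri]) * j(abs(rg$L[ri]))
    # keep each hour inside its regime's stability band
    L <- ifelse(regime == "neutral", sign(L) * pmax(abs(L), 501),
         ifelse(regime == "stable", pmin(pmax(L, 101), 500),
         ifelse(regime == "very stable", pmin(pmax(L, 2), 100),
                pmin(pmax(L, -500), -2))))
    u <- j(rg$u[ri])
    u <- pmax(u, 0.55)
    wdir <- (spec$prevailing_wdir + stats::rnorm(n, 0, spec$wdir_sd)) %% 360
    doy <- as.integer(format(ts, "%j"))
    temp_f <- 58 - 0.12 * (doy - min(doy)) + 9 * sin(2 * pi * (hod - 9) / 24) +
      stats::rnorm(n, 0, 2)
    calm <- stats::runif(n) < spec$calm_frac
    u[calm] <- stats::runif(sum(calm), 0.05, 0.45)
    miss <- stats::runif(n) < spec$missing_frac
    L[miss] <- NA_real_
    zic[regime %in% c("stable", "very stable")] <- NA_real_
    met_hours(tibble::tibble(
      timestamp = ts, ustar = ustar, L = L, zic = zic, zim = zim,
      z0 = rg$z0[ri], u = u, wdir = wdir, temp_f = temp_f))
  })
}

#' Generate the synthetic emission-factor table
#'
#' Complete axes (12 months x 11 temperature bins x 16 speed bins x 8
#' vehicle classes) for three pollutants: a diesel marker (`pm25_like`,
#' strong diesel/gasoline contrast), an intermediate (`nox_like`) and a
#' traffic marker (`co_like`, identical factors for every class, so fleet
#' composition has no effect). Factors follow a mild U-shaped speed curve
#' (highest at 2.5 mph, minimum at mid speeds), decrease gently with
#' temperature and carry a weak seasonal cycle. Deterministic (no random
#' draws).
#'
#' @param spec a `scenario_spec`.
#' @return An `ef_table`.
#' @export
make_ef_table <- function(spec = scenario_spec()) {
  g <- expand.grid(month = 1:12, pollutant = names(spec$ef_levels),
                   vclass = vehicle_classes(), temp_bin = temp_bins_f(),
                   speed_bin = speed_bins_mph(),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lev <- vapply(seq_len(nrow(g)), function(i) {
    ll <- spec$ef_levels[[g$pollutant[i]]]
    if (g$vclass[i] %in% diesel_classes()) ll[["diesel"]] else ll[["gasoline"]]
  }, numeric(1))
  speed_f <- 0.7 + 2.8 * exp(-g$speed_bin / 10) + 1e-4 * (g$speed_bin - 45)^2
  temp_f <- 1 + 0.004 * (50 - g$temp_bin)
  month_f <- 1 + 0.05 * cos(2 * pi * (g$month - 1) / 12)
  g$ef <- lev * speed_f * temp_f * month_f
  ef_table(g)
}

#' Generate synthetic temporal allocation factors
#'
#' Weekday hourly factors are bimodal (morning and evening rush peaks),
#' weekend factors single-moded in the afternoon; day-of-week factors are
#' higher on weekdays, and monthly factors carry a mild summer-high cycle.
#' All normalised onto the [taf_set()] convention.
#'
#' @param spec a `scenario_spec`.
#' @return A `taf_set`.
#' @export
make_tafs <- function(spec = scenario_spec()) {
  h <- 0:23
  bump <- function(centre, width) exp(-(h - centre)^2 / (2 * width^2))
  wd <- 0.35 + bump(spec$weekday_peaks[["am"]], 1.6) + bump(spec$weekday_peaks[["pm"]], 2.2)
  we <- 0.45 + 1.1 * bump(spec$weekend_peak, 3.5)
  dow <- c(1.05, 1.05, 1.05, 1.05, 1.1, 0.9, 0.8)
  mon <- 1 + 0.08 * cos(2 * pi * (1:12 - 7) / 12)
  taf_set(rbind(weekday = wd, weekend = we), dow, mon)
}

#' Generate synthetic permanent-traffic-recorder records
#'
#' One record per corridor (NFC 11/12) link for the study year. Measured
#' AADT embodies a model-vs-measured bias (`measured = model / (1 + bias)`,
#' bias centred on `ptr_interstate_bias` for interstates and 0 for
#' freeways). Measured commercial AADT implies diesel shares alternating
#' over `ptr_diesel_shares` on interstates (some interstate stretches carry
#' freeway-like diesel volumes) and the lower share on freeways.
#'
#' @param spec a `scenario_spec`.
#' @param links the network.
#' @param seed overrides `spec$seed`.
#' @param year measurement year.
#' @return A `ptr_records` object.
#' @export
make_ptr <- function(spec = scenario_spec(), links = make_network(spec),
                     seed = spec$seed, year = 2010L) {
  with_seed(seed + 3L, {
    ii <- which(links$nfc == 11L)
    ff <- which(links$nfc == 12L)
    bias_i <- stats::rnorm(length(ii), spec$ptr_interstate_bias, spec$ptr_bias_sd)
    bias_f <- stats::rnorm(length(ff), 0, spec$ptr_bias_sd)
    share_i <- rep_len(spec$ptr_diesel_shares, length(ii))
    share_f <- rep_len(min(spec$ptr_diesel_shares), length(ff))
    m_aadt <- c(links$aadt[ii] / (1 + bias_i), links$aadt[ff] / (1 + bias_f))
    ptr_records(tibble::tibble(
      link_id = c(links$id[ii], links$id[ff]),
      year = year,
      measured_aadt = m_aadt,
      measured_caadt = c(share_i, share_f) * m_aadt))
  })
}

#' Run the full synthetic scenario end to end
#'
#' Generates every input, computes hourly link emissions, the
#' unit-concentration matrix, receptor concentrations for every pollutant,
#' and cohort labels. The chi matrix is computed once; emissions
#' adjustments (see [apply_adjustments()]) reuse it unchanged.
#'
#' @param spec a `scenario_spec`.
#' @param seed overrides `spec$seed`.
#' @param constants dispersion constants.
#' @return List: spec, links, receptors (classified), met, ef, tafs, ptr,
#'   emissions, chi, conc (named list of `receptor_concentrations` per
#'   pollutant).
#' @export
run_scenario <- function(spec = scenario_spec(), seed = spec$seed,
                         constants = dispersion_constants()) {
  links <- make_network(spec, seed)
  recs <- make_participants(spec, links, seed)
  recs <- classify_receptors(recs, links)
  met <- make_met_series(spec, seed)
  ef <- make_ef_table(spec)
  tafs <- make_tafs(spec)
  ptr <- make_ptr(spec, links, seed)
  emis <- link_emissions(links, ef, urban_fleet_mixes(), tafs, met)
  chi <- build_chi_matrix(links, recs, met, constants)
  conc <- lapply(stats::setNames(ef$pollutants, ef$pollutants), function(pl) {
    combine_concentrations(chi, emis, pl)
  })
  list(spec = spec, links = links, receptors = recs, met = met, ef = ef,
       tafs = tafs, ptr = ptr, emissions = emis, chi = chi, conc = conc)
}

#' Apply the measurement-driven adjustments to a scenario run
#'
#' Rescales interstate AADT (VMT-conserving), reassigns fleet mixes from
#' the measured diesel shares, relabels the cohorts, recomputes emissions
#' and recombines them with the stored chi matrix (which is untouched).
#'
#' @param scn output of [run_scenario()].
#' @param interstate_factor see [rescale_aadt()].
#' @return List like [run_scenario()] plus `logs` (adjustment logs) and
#'   the adjusted links/receptors/emissions/concentrations.
#' @export
apply_adjustments <- function(scn, interstate_factor = 0.8) {
  r1 <- rescale_aadt(scn$links, interstate_factor)
  r2 <- reassign_diesel(r1$links, scn$ptr, urban_fleet_mixes())
  r3 <- relabel_cohorts(scn$receptors, r2$links)
  emis <- link_emissions(r2$links, scn$ef, urban_fleet_mixes(), scn$tafs, scn$met)
  conc <- lapply(stats::setNames(scn$ef$pollutants, scn$ef$pollutants), function(pl) {
    combine_concentrations(scn$chi, emis, pl)
  })
  list(links = r2$links, receptors = r3$receptors, emissions = emis,
       conc = conc, chi = scn$chi,
       logs = list(rescale = r1$log, diesel = r2$log, cohorts = r3$log))
}

#' Write a complete scenario directory
#'
#' Emits every input the pipeline readers consume: links (GeoJSON),
#' receptors, meteorology, emission factors, fleet mixes, temporal
#' allocation factors and traffic-recorder records.
#'
#' @param spec a `scenario_spec`.
#' @param dir output directory (created if needed).
#' @param seed overrides `spec$seed`.
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(spec = scenario_spec(), dir, seed = spec$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  links <- make_network(spec, seed)
  write_links(links, file.path(dir, "links.geojson"))
  write_receptors(make_participants(spec, links, seed), file.path(dir, "receptors.csv"))
  write_met(make_met_series(spec, seed), file.path(dir, "met.csv"))
  write_ef_table(make_ef_table(spec), file.path(dir, "ef_table.csv"))
  write_fleet_mixes(urban_fleet_mixes(), file.path(dir, "fleet_mixes.csv"))
  write_tafs(make_tafs(spec), file.path(dir, "tafs.csv"))
  write_ptr(make_ptr(spec, links, seed), file.path(dir, "ptr.csv"))
  invisible(dir)
}
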