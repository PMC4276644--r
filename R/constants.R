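#' Dispersion engine constants
#'
#' All tunable constants of the line-source dispersion engine in one place.
#' Defaults are the package's normative parameterisation of surface-layer
#' turbulence and plume growth; each may be overridden by passing a named
#' value, and the property suite (flux conservation, monotone decay,
#' stability ordering) is expected to hold for moderate retunings.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list with components:
#' \describe{
#'   \item{kappa}{von Karman constant (0.4).}
#'   \item{a_v, a_w}{mechanical turbulence coefficients: sigma_v = a_v*ustar,
#'     sigma_w = a_w*ustar before the convective contribution (1.9, 1.6; the
#'     vertical coefficient sits above the classical surface-layer 1.3 to
#'     absorb vehicle-induced turbulence over the roadway).}
#'   \item{b_conv}{convective contribution coefficient on wstar (0.6).}
#'   \item{sigma_v_min, sigma_w_min}{turbulence floors in m/s (0.2, 0.1).}
#'   \item{t_y}{lateral plume-growth time scale T_y in seconds (600).}
#'   \item{c_zs}{stable vertical time-scale coefficient: T_z = c_zs*|L|/sigma_w (2).}
#'   \item{c_zn}{neutral vertical time-scale coefficient: T_z = c_zn*z_mix/sigma_w (1.2).}
#'   \item{lid_factor}{sigma_z/z_mix ratio beyond which the vertical term is
#'     replaced by the well-mixed 1/z_mix limit (1.2).}
#'   \item{n_images}{number of mixing-lid image pairs on each side (2).}
#'   \item{x_min}{minimum downwind distance in metres for plume transport (1).}
#'   \item{h_src}{effective source height in metres (1.0, tailpipe/turbulent wake).}
#'   \item{z_rec}{default receptor (breathing) height in metres (1.5).}
#'   \item{tol}{relative tolerance of the adaptive line integration (1e-3).}
#'   \item{meander}{logical; include the low-wind meander component (TRUE).}
#'   \item{cos_cap}{effective-distance cap: receptors with transport/normal
#'     cosine at or below this are treated as upwind (0.1).}
#'   \item{n0, n_max}{initial and maximum element counts of the adaptive
#'     line integration (8, 65536).}
#' }
#' @export
#' @examples
#' cst <- dispersion_constants(meander = FALSE)
#' cst$t_y
dispersion_constants <- function(...) {
  cst <- list(
    kappa = 0.4,
    a_v = 1.9, a_w = 1.6, b_conv = 0.6,
    sigma_v_min = 0.2, sigma_w_min = 0.1,
    t_y = 600, c_zs = 2, c_zn = 1.2,
    lid_factor = 1.2, n_images = 2L,
    x_min = 1, h_src = 1.0, z_rec = 1.5,
    tol = 1e-3, meander = TRUE, cos_cap = 0.1,
    n0 = 8L, n_max = 65536L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cst))
    if (length(bad)) stop("unknown dispersion constant(s): ", paste(bad, collapse = ", "))
    cst[names(ov)] <- ov
  }
  cst
}

#' Urban national functional classes recognised by the pipeline
#'
#' @return Integer vector of valid NFC codes: 11 (interstate), 12 (other
#'   freeway), 14 (other principal arterial), 16 (minor arterial),
#'   17 (collector), 19 (local).
#' @export
nfc_classes <- function() c(11L, 12L, 14L, 16L, 17L, 19L)

#' Vehicle classes of the fleet-mix scheme
#'
#' The eight fuel/vehicle classes used by the emission-factor tables:
#' five gasoline (LDGV, LDGT1, LDGT2, HDGV, MC) and three diesel
#' (LDDV, LDDT, HDDV).
#'
#' @return Character vector of class abbreviations.
#' @export
vehicle_classes <- function() {
  c("LDGV", "LDGT1", "LDGT2", "HDGV", "MC", "LDDV", "LDDT", "HDDV")
}

#' Diesel vehicle classes
#' @return Character vector: LDDV, LDDT, HDDV.
#' @export
diesel_classes <- function() c("LDDV", "LDDT", "HDDV")

#' Default modelled time periods of day
#'
#' The five periods used for link speeds and exposure summaries:
#' Off-peak1 (00-06), AM-peak (07-08), Mid-day (09-15), PM-peak (16-18),
#' Off-peak2 (19-23). Hours are local clock hours, inclusive at both ends.
#'
#' @return A `time_periods` tibble with columns name, start_hour, end_hour.
#' @export
#' @examples
#' default_time_periods()
default_time_periods <- function() {
  time_periods(tibble::tibble(
    name = c("offpeak1", "ampeak", "midday", "pmpeak", "offpeak2"),
    start_hour = c(0L, 7L, 9L, 16L, 19L),
    end_hour = c(6L, 8L, 15L, 18L, 23L)
  ))
}

#' Packaged urban fleet-mix catalog
#'
#' Fleet mixes (percent of total activity by vehicle class) for the three
#' urban roadway groupings: `interstate` (NFC 11, high diesel),
#' `arterial` (NFC 12/14/16, low diesel) and `other` (NFC 17/19). Columns
#' are printed percentages and therefore sum to ~100 with rounding.
#'
#' @return Named list of `fleet_mix` objects.
#' @export
#' @examples
#' diesel_fraction(urban_fleet_mixes()$interstate)  # 9.18
urban_fleet_mixes <- function() {
  cls <- vehicle_classes()
  list(
    interstate = fleet_mix("interstate", stats::setNames(
      c(70.82, 11.59, 5.90, 2.21, 0.40, 0.98, 0.51, 7.69) / 100, cls)),
    arterial = fleet_mix("arterial", stats::setNames(
      c(75.66, 11.08, 5.64, 2.20, 0.20, 1.04, 0.49, 3.70) / 100, cls)),
    other = fleet_mix("other", stats::setNames(
      c(50.50, 24.98, 12.72, 1.15, 2.10, 0.70, 1.09, 6.75) / 100, cls))
  )
}

#' Representative surface meteorology for the four stability regimes
#'
#' One measured suburban fall hour for each stability regime, used as the
#' centre of the synthetic meteorology generator and as the standard set of
#' conditions for dispersion sensitivity checks. Convective mixing height
#' (zic) is undefined (NA) for the stably stratified regimes.
#'
#' @return Tibble with columns regime, ustar (m/s), zic (m), zim (m), L (m),
#'   z0 (m), u (m/s).
#' @export
#' @examples
#' stability_regimes()
stability_regimes <- function() {
  tibble::tibble(
    regime = c("convective", "neutral", "stable", "very stable"),
    ustar = c(0.229, 0.734, 0.254, 0.093),
    zic = c(80, 356, NA, NA),
    zim = c(252, 1445, 294, 137),
    L = c(-12.9, -1223.7, 104.5, 12.8),
    z0 = c(0.167, 0.48, 0.104, 0.104),
    u = c(1.65, 4.63, 2.66, 1.03)
  )
}

#' Build a complete MetHour record from one stability-regime row
#'
#' Convenience for tests and sensitivity runs: takes a row of
#' [stability_regimes()] and fills in a timestamp, wind direction and
#' temperature to form a valid hourly meteorology record.
#'
#' @param regime one of "convective", "neutral", "stable", "very stable".
#' @param wdir wind from-direction, degrees clockwise from north.
#' @param temp_f temperature, degrees Fahrenheit.
#' @param timestamp POSIXct hour.
#' @return One-row `met_hours` tibble.
#' @export
regime_met_hour <- function(regime, wdir = 270, temp_f = 50,
                            timestamp = as.POSIXct("2010-09-15 08:00:00", tz = "UTC")) {
  rg <- stability_regimes()
  row <- rg[rg$regime == regime, ]
  if (nrow(row) != 1L) stop("unknown regime: ", regime)
  met_hours(tibble::tibble(
    timestamp = timestamp, ustar = row$ustar, L = row$L, zic = row$zic,
    zim = row$zim, z0 = row$z0, u = row$u, wdir = wdir, temp_f = temp_f
  ))
}

mi_m <- 1609.344  # metres per mile
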