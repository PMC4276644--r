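# Unit-emission Gaussian line-source dispersion driven by Monin-Obukhov
# surface meteorology. The kernel itself lives in src/dispersion.cpp; this
# file holds the meteorological derivations, the user-facing surface and
# the chi-matrix container.

#' Classify atmospheric stability from the Monin-Obukhov length
#'
#' Four regimes: neutral (`|L| > 500`), stable (`100 < L <= 500`),
#' very stable (`0 < L <= 100`) and convective (`-500 <= L < 0`).
#'
#' @param L Monin-Obukhov length(s) in metres; finite and nonzero.
#' @return Character vector of "convective", "neutral", "stable",
#'   "very stable".
#' @export
#' @examples
#' classify_stability(c(-12.9, -1223.7, 104.5, 12.8))
classify_stability <- function(L) {
  if (any(!is.finite(L)) || any(L == 0)) stop("classify_stability: L must be finite and nonzero")
  ifelse(abs(L) > 500, "neutral",
         ifelse(L < 0, "convective",
                ifelse(L > 100, "stable", "very stable")))
}

stab_code <- function(stability) {
  c(convective = 0, neutral = 1, stable = 2, `very stable` = 2)[stability]
}

#' Derive dispersion meteorology from a surface record
#'
#' Computes the turbulence and transport quantities the plume kernel needs:
#' the convective velocity scale `wstar = ustar * (zic / (kappa |L|))^(1/3)`
#' (zero except in convective hours), horizontal and vertical turbulence
#' `sigma_v = max(sqrt((a_v ustar)^2 + (b_conv wstar)^2), sigma_v_min)` and
#' `sigma_w = max(sqrt((a_w ustar)^2 + (b_conv wstar)^2), sigma_w_min)`,
#' the effective transport speed `u_e = sqrt(u^2 + 2 sigma_v^2)` (never
#' below the mean wind, finite even in calms) and the mixing-lid height
#' `z_mix` (`max(zic, zim)` when `L < 0`, else `zim`).
#'
#' @param m a `met_hours` object (all rows must be complete).
#' @param constants see [dispersion_constants()].
#' @return A tibble with one row per hour: timestamp, wstar, sigma_v,
#'   sigma_w, u_e, z_mix, stability_class, plus carried L, u, wdir.
#' @export
#' @examples
#' derive_met(regime_met_hour("convective"))$wstar  # ~0.571
derive_met <- function(m, constants = dispersion_constants()) {
  if (!all(m$complete)) stop("derive_met: incomplete meteorology hour(s)")
  if (any(m$L == 0)) stop("derive_met: L = 0 is undefined")
  stability <- classify_stability(m$L)
  wstar <- ifelse(stability == "convective",
                  m$ustar * (m$zic / (constants$kappa * abs(m$L)))^(1 / 3), 0)
  sigma_v <- pmax(sqrt((constants$a_v * m$ustar)^2 + (constants$b_conv * wstar)^2),
                  constants$sigma_v_min)
  sigma_w <- pmax(sqrt((constants$a_w * m$ustar)^2 + (constants$b_conv * wstar)^2),
                  constants$sigma_w_min)
  z_mix <- ifelse(m$L < 0, pmax(ifelse(is.na(m$zic), 0, m$zic), m$zim), m$zim)
  tibble::tibble(
    timestamp = m$timestamp,
    wstar = wstar, sigma_v = sigma_v, sigma_w = sigma_w,
    u_e = sqrt(m$u^2 + 2 * sigma_v^2),
    z_mix = z_mix,
    stability_class = stability,
    L = m$L, u = m$u, wdir = m$wdir
  )
}

dmet_vector <- function(d) {
  c(d$sigma_v, d$sigma_w, d$u_e, d$z_mix, abs(d$L), stab_code(d$stability_class))
}

#' Plume spread as a function of downwind distance
#'
#' With travel time `t = x / u_e`: lateral spread
#' `sigma_y = sigma_v t (1 + t/T_y)^(-1/2)` and vertical spread
#' `sigma_z = sigma_w t g(t)`, where the damping `g` is
#' `(1 + t/T_z)^(-1/2)` with `T_z = c_zs |L| / sigma_w` in stable and very
#' stable hours, `T_z = c_zn z_mix / sigma_w` in neutral hours, and `g = 1`
#' (ballistic-then-linear growth unhindered below the lid) in convective
#' hours. Both spreads are strictly increasing in `x`.
#'
#' @param x downwind distance(s) in metres, > 0.
#' @param d one row of [derive_met()] output.
#' @param constants see [dispersion_constants()].
#' @return Tibble with columns sigma_y, sigma_z (metres).
#' @export
sigma_curves <- function(x, d, constants = dispersion_constants()) {
  if (any(x <= 0)) stop("sigma_curves: x must be > 0")
  t <- x / d$u_e
  sigma_y <- d$sigma_v * t / sqrt(1 + t / constants$t_y)
  code <- stab_code(d$stability_class)
  if (code == 2) {
    tz <- constants$c_zs * abs(d$L) / d$sigma_w
    g <- 1 / sqrt(1 + t / tz)
  } else if (code == 1) {
    tz <- constants$c_zn * d$z_mix / d$sigma_w
    g <- 1 / sqrt(1 + t / tz)
  } else {
    g <- 1
  }
  tibble::tibble(sigma_y = sigma_y, sigma_z = d$sigma_w * t * g)
}

#' Unit-emission concentration from one link at one receptor
#'
#' Numerically integrates the Gaussian point kernel along the link polyline
#' at a line-source strength of 1 g/m/s, in the hour's wind-aligned frame.
#' Elements downwind contribute a plume term; with meander enabled, all
#' elements additionally contribute a radially symmetric low-wind term, the
#' two blended by the meander fraction `min(1, 2 sigma_v^2 / u_e^2)`. The
#' vertical term carries ground and mixing-lid images and collapses to the
#' well-mixed `1/z_mix` limit once `sigma_z` exceeds `lid_factor * z_mix`.
#' Integration refines by successive node doubling to the relative
#' tolerance in `constants`.
#'
#' @param link one-row `road_links` subset or coordinate matrix.
#' @param receptor one-row `receptors` subset or numeric `c(x, y)`
#'   (receptor height then defaults to `constants$z_rec`).
#' @param m one-row complete `met_hours` subset.
#' @param constants see [dispersion_constants()].
#' @return chi in micrograms/m^3 per (g/m/s).
#' @export
unit_concentration <- function(link, receptor, m, constants = dispersion_constants()) {
  mat <- resolve_geometry(link)
  if (inherits(receptor, "data.frame")) {
    p <- c(receptor$x[1], receptor$y[1])
    z <- if ("height" %in% names(receptor)) receptor$height[1] else constants$z_rec
  } else {
    p <- as.numeric(receptor)
    z <- if (length(p) >= 3) p[3] else constants$z_rec
  }
  if (perpendicular_distance(mat, p[1:2]) < constants$x_min) {
    stop("unit_concentration: receptor lies on the link centerline (within x_min); undefined")
  }
  d <- derive_met(m[1, , drop = FALSE], constants)
  chi_point_cpp(mat, p[1], p[2], z, d$wdir, dmet_vector(d), constants)
}

#' Unit-concentration matrix over links, receptors and hours
#'
#' Runs the dispersion kernel for every link-receptor pair in every valid
#' hour (complete meteorology and wind speed >= 0.5 m/s; see
#' [hour_valid()]). Invalid hours are masked (NA), never zero-filled. The
#' result is independent of emissions, so emissions adjustments never
#' require recomputing it.
#'
#' @param links a `road_links` object.
#' @param recs a `receptors` object.
#' @param met a `met_hours` series.
#' @param constants see [dispersion_constants()].
#' @return A `chi_matrix`: list with `chi` (array link x receptor x hour,
#'   micrograms/m^3 per g/m/s), `link_ids`, `receptor_ids`, `timestamps`,
#'   `valid` (logical per hour).
#' @export
build_chi_matrix <- function(links, recs, met, constants = dispersion_constants()) {
  if (!nrow(links) || !nrow(recs)) stop("build_chi_matrix: empty link or receptor set")
  for (i in seq_len(nrow(links))) {
    dmin <- vapply(seq_len(nrow(recs)), function(j) {
      perpendicular_distance(links$geometry[[i]], c(recs$x[j], recs$y[j]))
    }, numeric(1))
    if (any(dmin < constants$x_min)) {
      stop("build_chi_matrix: receptor on the centerline of link ", links$id[i])
    }
  }
  valid <- hour_valid(met)
  n_h <- nrow(met)
  chi <- array(NA_real_, dim = c(nrow(links), nrow(recs), n_h))
  rec_xyz <- cbind(recs$x, recs$y,
                   if ("height" %in% names(recs)) recs$height else constants$z_rec)
  idx_valid <- which(valid)
  if (length(idx_valid)) {
    dmet <- derive_met(met[idx_valid, , drop = FALSE], constants)
    for (k in seq_along(idx_valid)) {
      d1 <- dmet[k, , drop = FALSE]
      chi[, , idx_valid[k]] <- chi_hour_cpp(links$geometry, rec_xyz, d1$wdir,
                                            dmet_vector(d1), constants)
    }
  }
  structure(list(chi = chi, link_ids = links$id, receptor_ids = recs$id,
                 timestamps = met$timestamp, valid = valid),
            class = "chi_matrix")
}

#' @export
print.chi_matrix <- function(x, ...) {
  cat(sprintf("<chi_matrix> %d links x %d receptors x %d hours (%d masked)\n",
              length(x$link_ids), length(x$receptor_ids), length(x$timestamps),
              sum(!x$valid)))
  invisible(x)
}

#' Read and write unit-concentration matrices (long CSV)
#'
#' One row per link, receptor and hour; masked hours carry empty chi.
#' Loss-free round trip with [build_chi_matrix()] output.
#'
#' @param path file path.
#' @return `read_chi` returns a `chi_matrix`.
#' @export
read_chi <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!inherits(df$timestamp, "POSIXct")) df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  attr(df$timestamp, "tzone") <- "UTC"
  link_ids <- unique(df$link_id)
  receptor_ids <- unique(df$receptor_id)
  timestamps <- unique(df$timestamp)
  chi <- array(NA_real_, dim = c(length(link_ids), length(receptor_ids), length(timestamps)))
  chi[cbind(match(df$link_id, link_ids), match(df$receptor_id, receptor_ids),
            match(df$timestamp, timestamps))] <- df$chi
  valid <- apply(chi, 3, function(sl) !all(is.na(sl)))
  structure(list(chi = chi, link_ids = link_ids, receptor_ids = receptor_ids,
                 timestamps = timestamps, valid = valid),
            class = "chi_matrix")
}

#' @rdname read_chi
#' @param cm a `chi_matrix`.
#' @export
write_chi <- function(cm, path) {
  n <- dim(cm$chi)
  df <- tibble::tibble(
    link_id = rep(cm$link_ids, times = n[2] * n[3]),
    receptor_id = rep(rep(cm$receptor_ids, each = n[1]), times = n[3]),
    timestamp = format(rep(cm$timestamps, each = n[1] * n[2]),
                       "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    chi = as.vector(cm$chi))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Normalise a concentration transect by its near-road value
#'
#' Divides every value of a distance-ordered transect by the value at the
#' receptor closest to the road, giving the dimensionless fall-off profile.
#'
#' @param chi_along_transect numeric vector ordered by distance from the
#'   road; the first value must be positive.
#' @return Dimensionless profile with first element 1.
#' @export
#' @examples
#' normalized_profile(c(10, 5, 2))  # 1.0 0.5 0.2
normalized_profile <- function(chi_along_transect) {
  if (!length(chi_along_transect) || chi_along_transect[1] <= 0) {
    stop("normalized_profile: first (near-road) value must be positive")
  }
  chi_along_transect / chi_along_transect[1]
}

#' Concentration-versus-distance transect for one meteorological hour
#'
#' Convenience around [unit_concentration()]: a long straight east-west
#' link with receptors on a perpendicular transect at the given distances;
#' the hour's wind direction is overridden so the wind blows perpendicular
#' to the road, from the road toward the receptors.
#'
#' @param m one-row complete `met_hours` subset.
#' @param distances downwind distances in metres (default 10-500 every 10).
#' @param link_length link length in metres (default 10 km).
#' @param constants see [dispersion_constants()].
#' @return Tibble with columns distance, chi.
#' @export
transect_profile <- function(m, distances = seq(10, 500, by = 10),
                             link_length = 10000,
                             constants = dispersion_constants()) {
  mat <- rbind(c(-link_length / 2, 0), c(link_length / 2, 0))
  m <- m[1, , drop = FALSE]
  m$wdir <- 0  # from the north; transport toward the southern transect
  chi <- vapply(distances, function(d) {
    unit_concentration(mat, c(0, -d), m, constants)
  }, numeric(1))
  tibble::tibble(distance = distances, chi = chi)
}
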