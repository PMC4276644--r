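# Emission-factor tables, fleet mixes, temporal allocation and hourly
# link emission rates.

temp_bins_f <- function() seq(0, 100, by = 10)
speed_bins_mph <- function() c(2.5, seq(5, 75, by = 5))

# Nearest-bin index with ties rounding to the upper bin; clamped at the ends.
nearest_bin <- function(value, bins) {
  mids <- (bins[-1] + bins[-length(bins)]) / 2
  findInterval(value, mids) + 1L
}

#' Emission-factor lookup table
#'
#' A dense lookup of per-vehicle emission factors (grams/vehicle/mile)
#' keyed by month (1-12), pollutant, vehicle class, temperature bin
#' (0-100 F by 10) and speed bin (2.5 mph, then 5-75 by 5). Every axis must
#' be complete for every pollutant present.
#'
#' @param df long data frame with columns month, pollutant, vclass,
#'   temp_bin, speed_bin, ef.
#' @return An `ef_table` object.
#' @export
ef_table <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("month", "pollutant", "vclass", "temp_bin", "speed_bin", "ef")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("ef_table: missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$ef < 0)) stop("ef_table: negative emission factor")
  if (!all(df$vclass %in% vehicle_classes())) stop("ef_table: unknown vehicle class")
  if (!all(df$temp_bin %in% temp_bins_f())) stop("ef_table: temp_bin off the 0-100 by 10 grid")
  if (!all(df$speed_bin %in% speed_bins_mph())) stop("ef_table: speed_bin off the bin grid")
  pollutants <- sort(unique(df$pollutant))
  dims <- c(12L, length(pollutants), length(vehicle_classes()),
            length(temp_bins_f()), length(speed_bins_mph()))
  arr <- array(NA_real_, dim = dims,
               dimnames = list(month = as.character(1:12), pollutant = pollutants,
                               vclass = vehicle_classes(),
                               temp_bin = as.character(temp_bins_f()),
                               speed_bin = as.character(speed_bins_mph())))
  idx <- cbind(df$month,
               match(df$pollutant, pollutants),
               match(df$vclass, vehicle_classes()),
               match(df$temp_bin, temp_bins_f()),
               match(df$speed_bin, speed_bins_mph()))
  if (anyDuplicated(idx)) stop("ef_table: duplicate keys")
  arr[idx] <- df$ef
  if (anyNA(arr)) {
    stop("ef_table: incomplete axes; every month/class/temperature/speed ",
         "combination must be present for each pollutant")
  }
  structure(list(arr = arr, pollutants = pollutants), class = "ef_table")
}

#' @export
print.ef_table <- function(x, ...) {
  cat(sprintf("<ef_table> pollutants: %s; %d entries\n",
              paste(x$pollutants, collapse = ", "), length(x$arr)))
  invisible(x)
}

#' @export
as_tibble.ef_table <- function(x, ...) {
  g <- expand.grid(month = 1:12, pollutant = x$pollutants,
                   vclass = vehicle_classes(), temp_bin = temp_bins_f(),
                   speed_bin = speed_bins_mph(),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$ef <- as.vector(x$arr)
  tibble::as_tibble(g)
}

#' Read and write emission-factor tables (long CSV)
#' @param path file path.
#' @return `read_ef_table` returns an `ef_table`.
#' @export
read_ef_table <- function(path) {
  ef_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_ef_table
#' @param table an `ef_table`.
#' @export
write_ef_table <- function(table, path) {
  readr::write_csv(as_tibble.ef_table(table), path, progress = FALSE)
  invisible(path)
}

#' Fleet mix
#'
#' Fractional composition of traffic by vehicle class. Fractions must be
#' non-negative and sum to 1 within rounding slack (printed percentage
#' columns sum to ~100); they are renormalised to exactly 1 inside
#' [composite_ef()], but [diesel_fraction()] reports the raw printed sum.
#'
#' @param name mix identifier.
#' @param fractions named numeric vector over [vehicle_classes()].
#' @return A `fleet_mix` object.
#' @export
fleet_mix <- function(name, fractions) {
  if (!length(fractions)) stop("fleet_mix: empty mix")
  bad <- setdiff(names(fractions), vehicle_classes())
  if (length(bad)) stop("fleet_mix: unknown class(es): ", paste(bad, collapse = ", "))
  if (any(fractions < 0)) stop("fleet_mix: negative fraction")
  s <- sum(fractions)
  if (s < 0.995 || s > 1.005) stop("fleet_mix: fractions sum to ", signif(s, 6), ", not ~1")
  full <- stats::setNames(numeric(length(vehicle_classes())), vehicle_classes())
  full[names(fractions)] <- fractions
  structure(list(name = name, fractions = full), class = "fleet_mix")
}

#' @export
print.fleet_mix <- function(x, ...) {
  cat(sprintf("<fleet_mix> %s (diesel %.2f%%)\n", x$name, diesel_fraction(x)))
  invisible(x)
}

#' Read and write fleet-mix catalogs (CSV: name, vclass, fraction)
#' @param path file path.
#' @return `read_fleet_mixes` returns a named list of `fleet_mix` objects.
#' @export
read_fleet_mixes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- lapply(split(df, df$name), function(d) {
    fleet_mix(d$name[1], stats::setNames(d$fraction, d$vclass))
  })
  out[unique(df$name)]
}

#' @rdname read_fleet_mixes
#' @param mixes named list of `fleet_mix` objects.
#' @export
write_fleet_mixes <- function(mixes, path) {
  df <- dplyr::bind_rows(lapply(mixes, function(m) {
    tibble::tibble(name = m$name, vclass = names(m$fractions), fraction = m$fractions)
  }))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Look up a vehicle-class emission factor
#'
#' Returns the table entry at the nearest temperature and speed bins
#' (ties round to the upper bin; values beyond the grid clamp to the
#' nearest end bin).
#'
#' @param table an `ef_table`.
#' @param pollutant,vclass table keys.
#' @param month calendar month 1-12.
#' @param temp_f temperature in Fahrenheit.
#' @param speed_mph link speed in miles/hour.
#' @return Emission factor in grams/vehicle/mile.
#' @export
lookup_ef <- function(table, pollutant, vclass, month, temp_f, speed_mph) {
  if (!month %in% 1:12) stop("lookup_ef: month must be in 1-12")
  ip <- match(pollutant, table$pollutants)
  if (is.na(ip)) stop("lookup_ef: pollutant not in table: ", pollutant)
  ic <- match(vclass, vehicle_classes())
  if (is.na(ic)) stop("lookup_ef: unknown vehicle class: ", vclass)
  table$arr[month, ip, ic,
            nearest_bin(temp_f, temp_bins_f()),
            nearest_bin(speed_mph, speed_bins_mph())]
}

#' Composite fleet-weighted emission factor
#'
#' The fraction-weighted sum of vehicle-class emission factors for a fleet
#' mix, the per-vehicle emission factor of the whole traffic stream.
#' Fractions are renormalised to sum exactly 1 before weighting, so the
#' composite is a convex combination of the class factors.
#'
#' @inheritParams lookup_ef
#' @param mix a `fleet_mix`.
#' @return A `composite_ef` object: list with `value` (g/vehicle/mile) and
#'   provenance fields (mix_name, pollutant, month, temp_bin, speed_bin).
#' @export
composite_ef <- function(table, mix, pollutant, month, temp_f, speed_mph) {
  if (!inherits(mix, "fleet_mix")) stop("composite_ef: mix must be a fleet_mix")
  w <- mix$fractions
  if (sum(w) <= 0) stop("composite_ef: empty mix")
  w <- w / sum(w)
  pos <- names(w)[w > 0]
  efs <- vapply(pos, function(cl) lookup_ef(table, pollutant, cl, month, temp_f, speed_mph),
                numeric(1))
  structure(list(
    value = sum(w[pos] * efs),
    mix_name = mix$name, pollutant = pollutant, month = month,
    temp_bin = temp_bins_f()[nearest_bin(temp_f, temp_bins_f())],
    speed_bin = speed_bins_mph()[nearest_bin(speed_mph, speed_bins_mph())]
  ), class = "composite_ef")
}

#' @export
print.composite_ef <- function(x, ...) {
  cat(sprintf("<composite_ef> %.4g g/veh/mi (%s, %s, month %d, %g F bin, %g mph bin)\n",
              x$value, x$pollutant, x$mix_name, x$month, x$temp_bin, x$speed_bin))
  invisible(x)
}

#' Diesel percentage of a fleet mix
#'
#' 100 times the summed LDDV + LDDT + HDDV fractions, using the raw
#' (unrenormalised) printed fractions so catalog percentages reproduce
#' exactly.
#'
#' @param mix a `fleet_mix`.
#' @return Diesel share in percent.
#' @export
#' @examples
#' diesel_fraction(urban_fleet_mixes()$interstate)  # 9.18
#' diesel_fraction(urban_fleet_mixes()$arterial)    # 5.23
diesel_fraction <- function(mix) {
  100 * sum(mix$fractions[diesel_classes()])
}

#' Fleet-to-fleet emission ratio
#'
#' Ratio of composite emission factors between two fleet mixes at the same
#' pollutant, month, temperature and speed. Activity and temporal factors
#' cancel, so this is the pure fleet-composition sensitivity of emissions.
#'
#' @inheritParams lookup_ef
#' @param mixA,mixB `fleet_mix` objects (numerator / denominator).
#' @return Dimensionless ratio.
#' @export
fleet_ratio <- function(table, mixA, mixB, pollutant, month, temp_f, speed_mph) {
  a <- composite_ef(table, mixA, pollutant, month, temp_f, speed_mph)$value
  b <- composite_ef(table, mixB, pollutant, month, temp_f, speed_mph)$value
  if (b == 0) stop("fleet_ratio: denominator composite emission factor is zero")
  a / b
}

# ---- temporal allocation ---------------------------------------------------

#' Temporal allocation factors
#'
#' Hour-of-day (by weekday/weekend), day-of-week and month-of-year factors
#' that turn AADT into hourly traffic volumes. Normalisation convention:
#' the 24 hourly factors of each day type sum to 1, and the day-of-week and
#' monthly factors each average 1, so AADT remains the annual-average daily
#' total.
#'
#' @param hourly 2 x 24 matrix with rownames "weekday"/"weekend"
#'   (columns = hours 0-23).
#' @param dow length-7 vector, Monday first.
#' @param month length-12 vector.
#' @param normalize if TRUE (default) rescale inputs onto the convention;
#'   if FALSE, inputs off the convention by more than 1e-9 are an error.
#' @return A `taf_set` object.
#' @export
taf_set <- function(hourly, dow, month, normalize = TRUE) {
  stopifnot(is.matrix(hourly), dim(hourly) == c(2L, 24L),
            setequal(rownames(hourly), c("weekday", "weekend")),
            length(dow) == 7L, length(month) == 12L,
            all(hourly >= 0), all(dow >= 0), all(month >= 0))
  if (normalize) {
    hourly <- hourly / rowSums(hourly)
    dow <- dow / mean(dow)
    month <- month / mean(month)
  } else {
    if (any(abs(rowSums(hourly) - 1) > 1e-9) || abs(mean(dow) - 1) > 1e-9 ||
        abs(mean(month) - 1) > 1e-9) {
      stop("taf_set: factors are not normalised (hourly sums 1; dow/month means 1)")
    }
  }
  structure(list(hourly = hourly[c("weekday", "weekend"), , drop = FALSE],
                 dow = unname(dow), month = unname(month)),
            class = "taf_set")
}

#' Uniform temporal allocation (every hour, day and month alike)
#' @return A `taf_set` with hourly = 1/24, dow = 1, month = 1.
#' @export
uniform_tafs <- function() {
  taf_set(matrix(1 / 24, 2, 24, dimnames = list(c("weekday", "weekend"), NULL)),
          rep(1, 7), rep(1, 12), normalize = FALSE)
}

#' Read and write temporal-allocation-factor files
#'
#' Single long CSV with columns component ("hourly", "dow", "month"),
#' key (day type for hourly; 1-7 Monday-first for dow; 1-12 for month),
#' hour (0-23 for hourly, empty otherwise) and factor.
#'
#' @param path file path.
#' @return `read_tafs` returns a `taf_set`.
#' @export
read_tafs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  h <- df[df$component == "hourly", ]
  hourly <- matrix(NA_real_, 2, 24, dimnames = list(c("weekday", "weekend"), NULL))
  hourly[cbind(match(h$key, rownames(hourly)), as.integer(h$hour) + 1L)] <- h$factor
  d <- df[df$component == "dow", ]
  m <- df[df$component == "month", ]
  taf_set(hourly,
          d$factor[order(as.integer(d$key))],
          m$factor[order(as.integer(m$key))])
}

#' @rdname read_tafs
#' @param tafs a `taf_set`.
#' @export
write_tafs <- function(tafs, path) {
  df <- dplyr::bind_rows(
    tibble::tibble(component = "hourly",
                   key = rep(c("weekday", "weekend"), each = 24),
                   hour = rep(0:23, times = 2),
                   factor = as.vector(t(tafs$hourly))),
    tibble::tibble(component = "dow", key = as.character(1:7), hour = NA_integer_,
                   factor = tafs$dow),
    tibble::tibble(component = "month", key = as.character(1:12), hour = NA_integer_,
                   factor = tafs$month)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

is_weekend <- function(timestamp) {
  as.POSIXlt(timestamp, tz = "UTC")$wday %in% c(0L, 6L)
}

#' Hourly traffic volume from AADT and temporal allocation
#'
#' `A = AADT * hourly(daytype, hour) * dow(day) * month(month)`, with the
#' weekend day type on Saturdays and Sundays.
#'
#' @param aadt annual average daily traffic (vehicles/day); scalar or
#'   vector recycled against `timestamp`.
#' @param tafs a `taf_set`.
#' @param timestamp POSIXct vector (UTC clock time).
#' @return Vehicles in the hour (same length as the longer input).
#' @export
hourly_activity <- function(aadt, tafs, timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  daytype <- ifelse(lt$wday %in% c(0L, 6L), "weekend", "weekday")
  dow_idx <- ifelse(lt$wday == 0L, 7L, lt$wday)  # Monday-first indexing
  aadt * tafs$hourly[cbind(match(daytype, rownames(tafs$hourly)), lt$hour + 1L)] *
    tafs$dow[dow_idx] * tafs$month[lt$mon + 1L]
}

#' Hourly emission rate for one link and hour
#'
#' Combines the composite fleet emission factor (at the link's time-period
#' speed and the hour's temperature) with the hourly traffic volume:
#' `e_per_mile = EF * A` in grams/mile over the hour, and the equivalent
#' line-source strength `q = e_per_mile / 1609.344 / 3600` in g/m/s. If the
#' hour's temperature is missing the emission is flagged missing (NA), not
#' zero.
#'
#' @param link one-row `road_links` subset.
#' @param table an `ef_table`.
#' @param mix a `fleet_mix`.
#' @param tafs a `taf_set`.
#' @param met_hour one-row `met_hours` subset supplying timestamp and
#'   temperature.
#' @param pollutant pollutant name.
#' @param periods `time_periods` for resolving the link speed.
#' @return One-row tibble: link_id, timestamp, pollutant, e_per_mile, q.
#' @export
link_emission_rate <- function(link, table, mix, tafs, met_hour, pollutant,
                               periods = default_time_periods()) {
  ts <- met_hour$timestamp[1]
  hr <- as.POSIXlt(ts, tz = "UTC")$hour
  speed <- link[[paste0("speed_", period_of_hour(periods, hr))]][1]
  if (is.null(speed) || is.na(speed)) stop("link speed unresolvable for period")
  temp <- met_hour$temp_f[1]
  if (is.na(temp)) {
    e <- NA_real_
  } else {
    month <- as.POSIXlt(ts, tz = "UTC")$mon + 1L
    ef <- composite_ef(table, mix, pollutant, month, temp, speed)$value
    e <- ef * hourly_activity(link$aadt[1], tafs, ts)
  }
  tibble::tibble(link_id = link$id[1], timestamp = ts, pollutant = pollutant,
                 e_per_mile = e, q = e / mi_m / 3600)
}

#' Hourly emissions for a whole network and meteorology series
#'
#' Vectorised application of [link_emission_rate()] over every link, hour
#' and pollutant. Each link uses the fleet mix named by its `mix_name`
#' column (resolved in `mixes`). Hours with missing temperature yield NA
#' emissions.
#'
#' @param links a `road_links` object.
#' @param table an `ef_table`.
#' @param mixes named list of `fleet_mix` objects covering the links'
#'   `mix_name` values.
#' @param tafs a `taf_set`.
#' @param met a `met_hours` series.
#' @param pollutants character vector; default all pollutants in `table`.
#' @param periods `time_periods`.
#' @return A `link_emissions` tibble: link_id, timestamp, pollutant,
#'   e_per_mile (g/mile in the hour), q (g/m/s).
#' @export
link_emissions <- function(links, table, mixes, tafs, met,
                           pollutants = table$pollutants,
                           periods = default_time_periods()) {
  miss <- setdiff(unique(links$mix_name), names(mixes))
  if (length(miss)) stop("link_emissions: no fleet mix named: ", paste(miss, collapse = ", "))
  lt <- as.POSIXlt(met$timestamp, tz = "UTC")
  month_h <- lt$mon + 1L
  tbin_h <- ifelse(is.na(met$temp_f), NA_integer_, nearest_bin(met$temp_f, temp_bins_f()))
  per_h <- period_of_hour(periods, lt$hour)
  act <- outer(links$aadt, hourly_activity(1, tafs, met$timestamp))  # links x hours

  # speed-bin index per link x hour via the period speed columns
  sp <- sapply(periods$name, function(p) links[[paste0("speed_", p)]])
  sp <- matrix(sp, nrow = nrow(links))  # links x periods
  sbin <- matrix(nearest_bin(sp, speed_bins_mph()), nrow = nrow(links))
  sbin_h <- sbin[, match(per_h, periods$name), drop = FALSE]  # links x hours

  # composite EF arrays per (mix, pollutant): month x tbin x sbin
  wts <- lapply(mixes, function(m) m$fractions / sum(m$fractions))
  comp <- list()
  for (mn in unique(links$mix_name)) {
    for (pl in pollutants) {
      ip <- match(pl, table$pollutants)
      if (is.na(ip)) stop("link_emissions: pollutant not in table: ", pl)
      w <- wts[[mn]]
      slices <- lapply(seq_along(vehicle_classes()),
                       function(ic) w[ic] * table$arr[, ip, ic, , ])
      comp[[paste(mn, pl, sep = "\r")]] <- Reduce(`+`, slices)  # 12 x 11 x 16
    }
  }

  n_l <- nrow(links); n_h <- nrow(met)
  out <- vector("list", length(pollutants))
  mix_l <- links$mix_name
  for (k in seq_along(pollutants)) {
    pl <- pollutants[k]
    e <- matrix(NA_real_, n_l, n_h)
    for (mn in unique(mix_l)) {
      rows <- which(mix_l == mn)
      ca <- comp[[paste(mn, pl, sep = "\r")]]
      hh <- which(!is.na(tbin_h))
      if (length(hh)) {
        idx <- cbind(rep(month_h[hh], each = length(rows)),
                     rep(tbin_h[hh], each = length(rows)),
                     as.vector(sbin_h[rows, hh, drop = FALSE]))
        e[rows, hh] <- ca[idx] * act[rows, hh]
      }
    }
    out[[k]] <- tibble::tibble(
      link_id = rep(links$id, times = n_h),
      timestamp = rep(met$timestamp, each = n_l),
      pollutant = pl,
      e_per_mile = as.vector(e),
      q = as.vector(e) / mi_m / 3600)
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("link_emissions", setdiff(class(res), "link_emissions")))
}

#' Read and write hourly link emissions (long CSV)
#' @param path file path.
#' @return `read_emissions` returns a `link_emissions` tibble.
#' @export
read_emissions <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!inherits(df$timestamp, "POSIXct")) df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  attr(df$timestamp, "tzone") <- "UTC"
  structure(df, class = c("link_emissions", setdiff(class(df), "link_emissions")))
}

#' @rdname read_emissions
#' @param emis a `link_emissions` tibble.
#' @export
write_emissions <- function(emis, path) {
  df <- tibble::as_tibble(emis)
  df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
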