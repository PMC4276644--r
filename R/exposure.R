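# Combining emissions with unit concentrations, validity and completeness
# rules, exposure summaries and cohort classification.

#' Hour validity for exposure calculations
#'
#' An hour is usable when the meteorology record is complete and the wind
#' speed is at least 0.5 m/s (slower winds are outside the Gaussian plume
#' framework's validity and are treated as missing, not zero).
#'
#' @param m a `met_hours` object.
#' @return Logical vector, one flag per hour.
#' @export
hour_valid <- function(m) {
  m$complete & !is.na(m$u) & m$u >= 0.5
}

#' Combine link emissions with unit concentrations
#'
#' The receptor concentration is the emissions-weighted sum of unit
#' concentrations over links: `C(receptor, hour) = sum_links q * chi`,
#' with `q` in g/m/s and `chi` in micrograms/m^3 per g/m/s. Hours masked in
#' the chi matrix, or with missing emissions, are invalid.
#'
#' @param chi a `chi_matrix`.
#' @param emissions a `link_emissions` tibble.
#' @param pollutant which pollutant to combine.
#' @return A `receptor_concentrations` tibble: receptor_id, timestamp,
#'   pollutant, c (micrograms/m^3), valid.
#' @export
combine_concentrations <- function(chi, emissions, pollutant) {
  emis <- emissions[emissions$pollutant == pollutant, ]
  if (!nrow(emis)) stop("combine_concentrations: no emissions for pollutant ", pollutant)
  extra <- setdiff(unique(emis$link_id), chi$link_ids)
  if (length(extra)) {
    stop("combine_concentrations: emissions reference link(s) absent from chi: ",
         paste(extra, collapse = ", "))
  }
  n_l <- length(chi$link_ids); n_r <- length(chi$receptor_ids)
  n_h <- length(chi$timestamps)
  q <- matrix(NA_real_, n_l, n_h)
  q[cbind(match(emis$link_id, chi$link_ids),
          match(emis$timestamp, chi$timestamps))] <- emis$q
  cmat <- matrix(NA_real_, n_r, n_h)
  valid_h <- chi$valid & colSums(is.na(q)) == 0L
  for (t in which(valid_h)) {
    cmat[, t] <- as.vector(crossprod(matrix(chi$chi[, , t], nrow = n_l), q[, t]))
  }
  structure(tibble::tibble(
    receptor_id = rep(chi$receptor_ids, times = n_h),
    timestamp = rep(chi$timestamps, each = n_r),
    pollutant = pollutant,
    c = as.vector(cmat),
    valid = rep(valid_h, each = n_r)
  ), class = c("receptor_concentrations", class(tibble::tibble())))
}

#' Read and write receptor concentration series (long CSV)
#' @param path file path.
#' @return `read_concentrations` returns a `receptor_concentrations` tibble.
#' @export
read_concentrations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!inherits(df$timestamp, "POSIXct")) df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  attr(df$timestamp, "tzone") <- "UTC"
  structure(df, class = c("receptor_concentrations", setdiff(class(df), "receptor_concentrations")))
}

#' @rdname read_concentrations
#' @param conc a `receptor_concentrations` tibble.
#' @export
write_concentrations <- function(conc, path) {
  df <- tibble::as_tibble(conc)
  df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

summary_stats <- function(x) {
  qs <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  tibble::tibble(min = min(x), p5 = qs[1], median = qs[2], mean = mean(x),
                 p95 = qs[3], max = max(x), n = length(x))
}

#' Period exposure summaries with a completeness rule
#'
#' For every receptor, day and time period (plus a whole-day "daily"
#' period), the mean of valid hourly concentrations is reported only when
#' the fraction of valid hours in that day-period cell is at least
#' `completeness` (default 75%, inclusive). Distribution statistics
#' (min, 5th percentile, median, mean, 95th percentile, max) are then
#' computed per receptor and period over the reported day cells.
#'
#' @param series a `receptor_concentrations` tibble.
#' @param periods a `time_periods` object.
#' @param completeness required valid-hour fraction in (0, 1].
#' @param daily also compute the 24-hour daily cells (default TRUE).
#' @return A `period_summary` list: `cells` (per receptor-day-period means
#'   with valid-hour counts and the reported flag) and `stats` (per
#'   receptor-period distribution statistics over reported days).
#' @export
period_average <- function(series, periods = default_time_periods(),
                           completeness = 0.75, daily = TRUE) {
  stopifnot(completeness > 0, completeness <= 1)
  df <- tibble::as_tibble(series)
  lt <- as.POSIXlt(df$timestamp, tz = "UTC")
  df$date <- as.Date(df$timestamp, tz = "UTC")
  df$period <- period_of_hour(periods, lt$hour)
  plen <- stats::setNames(periods$end_hour - periods$start_hour + 1L, periods$name)
  cells <- df |>
    dplyr::group_by(.data$receptor_id, .data$date, .data$period) |>
    dplyr::summarise(
      n_valid = sum(.data$valid),
      mean_c = ifelse(sum(.data$valid) > 0, mean(.data$c[.data$valid]), NA_real_),
      .groups = "drop") |>
    dplyr::mutate(n_hours = unname(plen[.data$period]),
                  reported = .data$n_valid / .data$n_hours >= completeness,
                  mean_c = ifelse(.data$reported, .data$mean_c, NA_real_))
  if (daily) {
    dcells <- df |>
      dplyr::group_by(.data$receptor_id, .data$date) |>
      dplyr::summarise(
        n_valid = sum(.data$valid),
        mean_c = ifelse(sum(.data$valid) > 0, mean(.data$c[.data$valid]), NA_real_),
        .groups = "drop") |>
      dplyr::mutate(period = "daily", n_hours = 24L,
                    reported = .data$n_valid / .data$n_hours >= completeness,
                    mean_c = ifelse(.data$reported, .data$mean_c, NA_real_))
    cells <- dplyr::bind_rows(cells, dcells)
  }
  stats <- cells |>
    dplyr::filter(.data$reported) |>
    dplyr::group_by(.data$receptor_id, .data$period) |>
    dplyr::reframe(summary_stats(.data$mean_c))
  structure(list(cells = cells, stats = stats), class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("<period_summary> %d day-period cells (%d reported), %d receptor-period stats\n",
              nrow(x$cells), sum(x$cells$reported), nrow(x$stats)))
  invisible(x)
}

#' Pooled hourly statistics by cohort and period
#'
#' Pools valid hourly concentrations across all receptors of each cohort
#' and computes distribution statistics per cohort and time period, plus an
#' "all" row per cohort over every valid hour.
#'
#' @param series a `receptor_concentrations` tibble.
#' @param groups tibble/data frame with columns receptor_id, group_label.
#' @param periods a `time_periods` object.
#' @return Tibble with group_label, period and the summary statistics.
#' @export
cohort_hourly_stats <- function(series, groups, periods = default_time_periods()) {
  df <- tibble::as_tibble(series)
  groups <- tibble::as_tibble(groups)
  if (!"receptor_id" %in% names(groups) && "id" %in% names(groups)) {
    groups$receptor_id <- groups$id
  }
  df <- dplyr::inner_join(df, groups[c("receptor_id", "group_label")], by = "receptor_id")
  df <- df[df$valid & !is.na(df$c), ]
  df$period <- period_of_hour(periods, as.POSIXlt(df$timestamp, tz = "UTC")$hour)
  by_period <- df |>
    dplyr::group_by(.data$group_label, .data$period) |>
    dplyr::reframe(summary_stats(.data$c))
  overall <- df |>
    dplyr::group_by(.data$group_label) |>
    dplyr::reframe(summary_stats(.data$c)) |>
    dplyr::mutate(period = "all", .after = "group_label")
  dplyr::bind_rows(by_period, overall)
}

#' Classify receptors into traffic/diesel exposure cohorts
#'
#' A receptor is HTHD when within `near_m` of any high-traffic high-diesel
#' link, else HTLD when within `near_m` of any high-traffic low-diesel
#' link, else LT (high-diesel takes precedence when both are in range).
#' High traffic means AADT at or above `ht_aadt_min`; the HD/LD designation
#' comes from the links' `diesel_group` column (by default NFC 11 = HD,
#' NFC 12 = LD). Also records the nearest high-traffic link, its distance,
#' and whether the receptor is within `verynear_m` of it.
#'
#' @param recs a `receptors` object.
#' @param links a `road_links` object.
#' @param ht_aadt_min high-traffic AADT threshold (vehicles/day).
#' @param near_m classification radius in metres.
#' @param verynear_m reported sub-flag radius in metres.
#' @return The receptors tibble with group_label replaced and columns
#'   nearest_ht_link, nearest_ht_distance, within_verynear added.
#' @export
classify_receptors <- function(recs, links, ht_aadt_min = 50000,
                               near_m = 300, verynear_m = 150) {
  ht <- links[links$aadt >= ht_aadt_min & !is.na(links$diesel_group), ]
  out <- tibble::as_tibble(recs)
  n <- nrow(out)
  out$group_label <- rep("LT", n)
  out$nearest_ht_link <- NA_character_
  out$nearest_ht_distance <- NA_real_
  out$within_verynear <- FALSE
  if (nrow(ht)) {
    dmat <- vapply(seq_len(nrow(ht)), function(i) {
      vapply(seq_len(n), function(j) {
        perpendicular_distance(ht$geometry[[i]], c(out$x[j], out$y[j]))
      }, numeric(1))
    }, numeric(n))
    dmat <- matrix(dmat, nrow = n)  # receptors x ht links
    hd <- which(ht$diesel_group == "HD")
    ld <- which(ht$diesel_group == "LD")
    d_hd <- if (length(hd)) apply(dmat[, hd, drop = FALSE], 1, min) else rep(Inf, n)
    d_ld <- if (length(ld)) apply(dmat[, ld, drop = FALSE], 1, min) else rep(Inf, n)
    out$group_label <- ifelse(d_hd <= near_m, "HTHD",
                              ifelse(d_ld <= near_m, "HTLD", "LT"))
    nearest <- apply(dmat, 1, which.min)
    out$nearest_ht_link <- as.character(ht$id)[nearest]
    out$nearest_ht_distance <- dmat[cbind(seq_len(n), nearest)]
    out$within_verynear <- out$nearest_ht_distance <= verynear_m
  }
  receptors(out)
}

#' Concentration and effective-distance summary per receptor
#'
#' For each receptor: the mean concentration over valid hours, and the
#' mean effective distance to its nearest high-traffic link over the valid
#' hours in which the receptor is downwind of that link (upwind hours are
#' excluded from the average; a receptor with no downwind hours gets NA
#' effective distance but still reports its mean concentration).
#'
#' @param conc a `receptor_concentrations` tibble.
#' @param recs a classified `receptors` object (see [classify_receptors()];
#'   `nearest_ht_link` must be present).
#' @param links a `road_links` object.
#' @param met the `met_hours` series supplying hourly wind directions.
#' @param cos_cap upwind cutoff cosine (see [effective_distance()]).
#' @return Tibble: receptor_id, group_label, perpendicular and mean
#'   effective distance (m), n_downwind, mean_c.
#' @export
distance_decay_profile <- function(conc, recs, links, met,
                                   cos_cap = dispersion_constants()$cos_cap) {
  if (!"nearest_ht_link" %in% names(recs)) {
    stop("distance_decay_profile: receptors must be classified first")
  }
  df <- tibble::as_tibble(conc)
  wdir <- stats::setNames(met$wdir, format(met$timestamp, "%Y-%m-%d %H", tz = "UTC"))
  valid_ts <- met$timestamp[hour_valid(met)]
  rows <- lapply(seq_len(nrow(recs)), function(j) {
    rid <- recs$id[j]
    sub <- df[df$receptor_id == rid & df$valid & !is.na(df$c), ]
    mean_c <- if (nrow(sub)) mean(sub$c) else NA_real_
    lid <- recs$nearest_ht_link[j]
    d_eff <- NA_real_; n_down <- 0L; d_perp <- NA_real_
    if (!is.na(lid)) {
      geom <- links$geometry[[match(lid, as.character(links$id))]]
      p <- c(recs$x[j], recs$y[j])
      d_perp <- perpendicular_distance(geom, p)
      w <- wdir[format(intersect_pos(valid_ts, sub$timestamp), "%Y-%m-%d %H", tz = "UTC")]
      de <- vapply(w, function(wd) effective_distance(geom, p, wd %% 360, cos_cap),
                   numeric(1))
      n_down <- sum(!is.na(de))
      if (n_down > 0) d_eff <- mean(de, na.rm = TRUE)
    }
    tibble::tibble(receptor_id = rid, group_label = recs$group_label[j],
                   perpendicular_distance = d_perp,
                   mean_effective_distance = d_eff, n_downwind = n_down,
                   mean_c = mean_c)
  })
  dplyr::bind_rows(rows)
}

# POSIXct intersection preserving class (base intersect strips it)
intersect_pos <- function(a, b) a[a %in% b]
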