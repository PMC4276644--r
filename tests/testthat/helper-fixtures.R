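# Shared fixtures, built in code at test time.

# One complete meteorology hour from explicit surface values.
met_row <- function(ustar, L, zic, zim, z0, u, wdir = 0, temp_f = 50,
                    timestamp = as.POSIXct("2010-09-15 08:00:00", tz = "UTC")) {
  met_hours(tibble::tibble(timestamp = timestamp, ustar = ustar, L = L,
                           zic = zic, zim = zim, z0 = z0, u = u,
                           wdir = wdir, temp_f = temp_f))
}

# Straight two-vertex link as a road_links row.
straight_link <- function(id = "L1", x0 = 0, y0 = 0, x1 = 1000, y1 = 0,
                          nfc = 11L, aadt = 80000, speed = 55) {
  road_links(tibble::tibble(
    id = id, nfc = nfc, aadt = aadt,
    speed_offpeak1 = speed, speed_ampeak = speed, speed_midday = speed,
    speed_pmpeak = speed,
    geometry = list(rbind(c(x0, y0), c(x1, y1)))))
}

# Two-class toy EF table: every (month, temp, speed) cell has ef_diesel for
# the diesel classes and ef_gas for the gasoline classes.
toy_ef_table <- function(ef_diesel = 0.3, ef_gas = 0.01,
                         pollutant = "pm25_like") {
  g <- expand.grid(month = 1:12, pollutant = pollutant,
                   vclass = vehicle_classes(), temp_bin = seq(0, 100, 10),
                   speed_bin = c(2.5, seq(5, 75, 5)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$ef <- ifelse(g$vclass %in% diesel_classes(), ef_diesel, ef_gas)
  ef_table(g)
}

# Hand-buildable chi_matrix for combination tests.
toy_chi <- function(chi_array, link_ids, receptor_ids, timestamps,
                    valid = rep(TRUE, length(timestamps))) {
  structure(list(chi = chi_array, link_ids = link_ids,
                 receptor_ids = receptor_ids, timestamps = timestamps,
                 valid = valid), class = "chi_matrix")
}

hours_utc <- function(start, n) {
  as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1L)
}
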