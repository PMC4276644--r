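#' Time-period partition of the day
#'
#' Validates and classes an ordered table of named periods. Periods must
#' cover hours 0-23 exactly once (inclusive start/end clock hours).
#'
#' @param df data frame with columns name, start_hour, end_hour.
#' @return A `time_periods` tibble.
#' @seealso [default_time_periods()]
#' @export
time_periods <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("name", "start_hour", "end_hour") %in% names(df)))
  hrs <- unlist(Map(seq, df$start_hour, df$end_hour))
  if (length(hrs) != 24L || !setequal(hrs, 0:23) || anyDuplicated(hrs)) {
    stop("time periods must partition hours 0-23 exactly once")
  }
  if (anyDuplicated(df$name)) stop("duplicate period names")
  structure(df, class = c("time_periods", class(df)))
}

#' Map clock hours to period names
#'
#' @param periods a `time_periods` object.
#' @param hour integer vector of clock hours (0-23).
#' @return Character vector of period names.
#' @export
period_of_hour <- function(periods, hour) {
  stopifnot(all(hour %in% 0:23))
  lut <- character(24)
  for (i in seq_len(nrow(periods))) {
    lut[(periods$start_hour[i]:periods$end_hour[i]) + 1L] <- periods$name[i]
  }
  lut[hour + 1L]
}

speed_cols <- function(periods) paste0("speed_", periods$name)

#' Road-link set
#'
#' Constructs and validates the central link table. Each link is a polyline
#' roadway segment in projected metre coordinates carrying uniform traffic
#' attributes: an NFC roadway class, annual average daily traffic (AADT,
#' vehicles/day) and a speed (miles/hour) for every modelled time period.
#'
#' @param df data frame with columns id, nfc, aadt, one speed column per
#'   period (`speed_<period>`), and a `geometry` list column of n x 2
#'   coordinate matrices (>= 2 vertices, projected metres). If only one of
#'   speed_offpeak1/speed_offpeak2 is present the other is filled from it
#'   (the two off-peak periods share speeds). Optional columns
#'   `diesel_group` ("HD"/"LD"/NA) and `mix_name` control diesel grouping
#'   and fleet-mix assignment; when absent they are derived from NFC
#'   (11 = HD/interstate mix, 12 = LD/arterial mix, 14/16 = arterial,
#'   17/19 = other).
#' @param periods the `time_periods` the speed columns refer to.
#' @return A `road_links` tibble with a derived `length` column (metres).
#' @export
road_links <- function(df, periods = default_time_periods()) {
  df <- tibble::as_tibble(df)
  req <- c("id", "nfc", "aadt", "geometry")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("road_links: missing column(s): ", paste(miss, collapse = ", "))
  if (!"speed_offpeak2" %in% names(df) && "speed_offpeak1" %in% names(df)) {
    df$speed_offpeak2 <- df$speed_offpeak1
  }
  if (!"speed_offpeak1" %in% names(df) && "speed_offpeak2" %in% names(df)) {
    df$speed_offpeak1 <- df$speed_offpeak2
  }
  sc <- speed_cols(periods)
  miss <- setdiff(sc, names(df))
  if (length(miss)) stop("road_links: missing speed column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("road_links: duplicate link ids")
  bad <- setdiff(unique(df$nfc), nfc_classes())
  if (length(bad)) stop("road_links: unknown NFC class(es): ", paste(bad, collapse = ", "))
  if (any(df$aadt < 0)) stop("road_links: negative AADT")
  for (s in sc) if (any(df[[s]] <= 0)) stop("road_links: non-positive speed in ", s)
  if (!is.list(df$geometry)) stop("road_links: geometry must be a list of coordinate matrices")
  df$length <- vapply(df$geometry, polyline_length, numeric(1))
  if (any(df$length <= 0)) stop("road_links: zero-length geometry")
  if (!"diesel_group" %in% names(df)) {
    df$diesel_group <- ifelse(df$nfc == 11L, "HD", ifelse(df$nfc == 12L, "LD", NA_character_))
  }
  if (!"mix_name" %in% names(df)) {
    df$mix_name <- unname(c(`11` = "interstate", `12` = "arterial", `14` = "arterial",
                            `16` = "arterial", `17` = "other", `19` = "other")[as.character(df$nfc)])
  }
  structure(df, class = c("road_links", setdiff(class(df), "road_links")))
}

#' @export
print.road_links <- function(x, ...) {
  cat(sprintf("<road_links> %d links, %.1f km network, NFC {%s}\n",
              nrow(x), sum(x$length) / 1000,
              paste(sort(unique(x$nfc)), collapse = ",")))
  NextMethod()
}

#' Receptor (participant location) set
#'
#' @param df data frame with columns id, x, y (projected metres; same CRS as
#'   the links). Optional: height (m above ground, default 1.5) and
#'   group_label (default "unassigned").
#' @return A `receptors` tibble.
#' @export
receptors <- function(df) {
  df <- tibble::as_tibble(df)
  miss <- setdiff(c("id", "x", "y"), names(df))
  if (length(miss)) stop("receptors: missing column(s): ", paste(miss, collapse = ", "))
  if (!"height" %in% names(df)) df$height <- 1.5
  if (!"group_label" %in% names(df)) df$group_label <- "unassigned"
  if (any(df$height < 0)) stop("receptors: negative height")
  if (anyDuplicated(df$id)) stop("receptors: duplicate ids")
  ok <- c("HTHD", "HTLD", "LT", "HD to LD", "unassigned")
  bad <- setdiff(unique(df$group_label), ok)
  if (length(bad)) stop("receptors: unknown group label(s): ", paste(bad, collapse = ", "))
  structure(df, class = c("receptors", setdiff(class(df), "receptors")))
}

#' Permanent-traffic-recorder records
#'
#' Measured AADT (and optionally commercial AADT, the heavy/commercial
#' portion used as a diesel-volume proxy) at fixed roadside counters.
#'
#' @param df data frame with columns link_id, year, measured_aadt and
#'   optionally measured_caadt (NA when not measured).
#' @return A `ptr_records` tibble.
#' @export
ptr_records <- function(df) {
  df <- tibble::as_tibble(df)
  miss <- setdiff(c("link_id", "year", "measured_aadt"), names(df))
  if (length(miss)) stop("ptr_records: missing column(s): ", paste(miss, collapse = ", "))
  if (!"measured_caadt" %in% names(df)) df$measured_caadt <- NA_real_
  if (any(df$measured_aadt < 0)) stop("ptr_records: negative measured AADT")
  has <- !is.na(df$measured_caadt)
  if (any(df$measured_caadt[has] < 0) ||
      any(df$measured_caadt[has] > df$measured_aadt[has])) {
    stop("ptr_records: measured CAADT must lie in [0, measured AADT]")
  }
  structure(df, class = c("ptr_records", setdiff(class(df), "ptr_records")))
}

# ---- readers / writers -----------------------------------------------------

check_projected <- function(coords) {
  # coords: matrix of all vertex coordinates
  if (all(abs(coords[, 1]) <= 180) && all(abs(coords[, 2]) <= 90)) {
    stop("coordinates look geographic (degrees); reproject links and receptors ",
         "to a projected CRS in metres before loading")
  }
  invisible(TRUE)
}

wkt_linestring <- function(mat) {
  paste0("LINESTRING (",
         paste(sprintf("%.6f %.6f", mat[, 1], mat[, 2]), collapse = ", "), ")")
}

parse_wkt_linestring <- function(s) {
  m <- regmatches(s, regexec("^\\s*LINESTRING\\s*\\((.*)\\)\\s*$", s, ignore.case = TRUE))[[1]]
  if (length(m) != 2L) stop("malformed WKT LINESTRING: ", s)
  parts <- strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+")
  xy <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (nrow(xy) < 2L || anyNA(xy)) stop("malformed WKT LINESTRING: ", s)
  unname(xy)
}

#' Read and write road-link files
#'
#' Two loss-free formats: GeoJSON (a FeatureCollection of LineString
#' features whose properties carry id/nfc/aadt/speed_* and optional
#' diesel_group/mix_name) and CSV with a WKT `geometry` column. Coordinates
#' must be in a projected CRS in metres; files whose coordinates all fall in
#' the longitude/latitude degree range are rejected with instructions to
#' reproject. Unknown NFC codes are rejected.
#'
#' @param path file path.
#' @param format "geojson" or "csv"; default guessed from the extension.
#' @param periods the `time_periods` the speed columns refer to.
#' @return `read_links` returns a `road_links` object; `write_links`
#'   (invisibly) the path.
#' @export
read_links <- function(path, format = guess_format(path), periods = default_time_periods()) {
  format <- match.arg(format, c("geojson", "csv"))
  if (format == "geojson") {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
    rows <- lapply(gj$features, function(ft) {
      if (!identical(ft$geometry$type, "LineString")) {
        stop("only LineString features are supported")
      }
      props <- lapply(ft$properties, function(v) if (is.null(v)) NA else v)
      tibble::as_tibble(props)
    })
    df <- dplyr::bind_rows(rows)
    df$geometry <- lapply(gj$features, function(ft) {
      xy <- do.call(rbind, lapply(ft$geometry$coordinates, function(p) as.numeric(p[1:2])))
      if (nrow(xy) < 2L) stop("LineString needs >= 2 vertices")
      xy
    })
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"geometry" %in% names(df)) stop("CSV link file needs a WKT 'geometry' column")
    df$geometry <- lapply(df$geometry, parse_wkt_linestring)
  }
  check_projected(do.call(rbind, df$geometry))
  df$nfc <- as.integer(df$nfc)
  road_links(df, periods = periods)
}

#' @rdname read_links
#' @param links a `road_links` object.
#' @export
write_links <- function(links, path, format = guess_format(path)) {
  format <- match.arg(format, c("geojson", "csv"))
  props <- links[setdiff(names(links), c("geometry", "length"))]
  if (format == "geojson") {
    features <- lapply(seq_len(nrow(links)), function(i) {
      list(
        type = "Feature",
        properties = as.list(props[i, ]),
        geometry = list(
          type = "LineString",
          coordinates = lapply(seq_len(nrow(links$geometry[[i]])),
                               function(j) as.numeric(links$geometry[[i]][j, ]))
        )
      )
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    out <- props
    out$geometry <- vapply(links$geometry, wkt_linestring, character(1))
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) "geojson" else "csv"
}

#' Read and write receptor CSV files
#' @param path file path.
#' @return `read_receptors` returns a `receptors` object.
#' @export
read_receptors <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_projected(cbind(df$x, df$y))
  receptors(df)
}

#' @rdname read_receptors
#' @param recs a `receptors` object.
#' @export
write_receptors <- function(recs, path) {
  readr::write_csv(tibble::as_tibble(recs), path, progress = FALSE)
  invisible(path)
}

#' Read and write permanent-traffic-recorder CSV files
#' @param path file path.
#' @return `read_ptr` returns a `ptr_records` object.
#' @export
read_ptr <- function(path) {
  ptr_records(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_ptr
#' @param ptr a `ptr_records` object.
#' @export
write_ptr <- function(ptr, path) {
  readr::write_csv(tibble::as_tibble(ptr), path, progress = FALSE)
  invisible(path)
}
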