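#' Hourly surface meteorology
#'
#' Validates and classes an hourly meteorology table with the surface-layer
#' variables the dispersion engine needs: friction velocity `ustar` (m/s),
#' Monin-Obukhov length `L` (m), convective and mechanical mixing heights
#' `zic`/`zim` (m), roughness length `z0` (m), wind speed `u` (m/s), wind
#' from-direction `wdir` (degrees clockwise from north) and temperature
#' `temp_f` (F, used by the emission-factor lookup). Hours with any missing
#' required field are flagged `complete = FALSE` and retained, never
#' dropped; `zic` is only required for convectively stratified hours
#' (`L < 0`).
#'
#' @param df data frame with columns timestamp, ustar, L, zic, zim, z0, u,
#'   wdir, temp_f.
#' @return A `met_hours` tibble with an added logical `complete` column.
#' @export
met_hours <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("timestamp", "ustar", "L", "zic", "zim", "z0", "u", "wdir", "temp_f")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("met_hours: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$timestamp)) stop("met_hours: duplicate timestamps")
  need_zic <- !is.na(df$L) & df$L < 0
  df$complete <- !is.na(df$ustar) & !is.na(df$L) & !is.na(df$zim) & !is.na(df$z0) &
    !is.na(df$u) & !is.na(df$wdir) & !is.na(df$temp_f) &
    (!need_zic | !is.na(df$zic))
  cc <- df[df$complete, ]
  if (nrow(cc)) {
    if (any(cc$ustar <= 0) || any(cc$zim <= 0) || any(cc$z0 <= 0) || any(cc$u < 0)) {
      stop("met_hours: complete hours must have ustar > 0, zim > 0, z0 > 0, u >= 0")
    }
  }
  structure(df, class = c("met_hours", setdiff(class(df), "met_hours")))
}

#' @export
print.met_hours <- function(x, ...) {
  cat(sprintf("<met_hours> %d hours (%d incomplete)\n", nrow(x), sum(!x$complete)))
  NextMethod()
}

sfc_sentinel <- -999

#' Read and write hourly surface meteorology
#'
#' Two formats. `csv`: columns timestamp (parsed in UTC), ustar, L, zic,
#' zim, z0, u, wdir, temp_f, with empty cells for missing values.
#' `sfc`: a whitespace-delimited surface-file subset in the style of
#' AERMET output, with columns year month day hour(1-24) ustar L zic zim z0
#' wdir u temp_f and the sentinel -999 for missing values.
#'
#' @param path file path.
#' @param format "csv" or "sfc"; default guessed from the extension
#'   (`.sfc` selects the surface format).
#' @return `read_met` returns a `met_hours` object.
#' @export
read_met <- function(path, format = if (grepl("\\.sfc$", path, ignore.case = TRUE)) "sfc" else "csv") {
  format <- match.arg(format, c("csv", "sfc"))
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!inherits(df$timestamp, "POSIXct")) {
      df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
    } else {
      attr(df$timestamp, "tzone") <- "UTC"
    }
  } else {
    cols <- c("year", "month", "day", "hour", "ustar", "L", "zic", "zim",
              "z0", "wdir", "u", "temp_f")
    df <- utils::read.table(path, col.names = cols)
    for (v in cols[-(1:4)]) df[[v]][df[[v]] == sfc_sentinel] <- NA_real_
    df$timestamp <- as.POSIXct(
      sprintf("%04d-%02d-%02d %02d:00:00", df$year, df$month, df$day, df$hour - 1L),
      tz = "UTC")
    df <- df[c("timestamp", "ustar", "L", "zic", "zim", "z0", "u", "wdir", "temp_f")]
  }
  met_hours(df)
}

#' @rdname read_met
#' @param met a `met_hours` object.
#' @export
write_met <- function(met, path, format = if (grepl("\\.sfc$", path, ignore.case = TRUE)) "sfc" else "csv") {
  format <- match.arg(format, c("csv", "sfc"))
  df <- tibble::as_tibble(met)
  df$complete <- NULL
  if (format == "csv") {
    df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    readr::write_csv(df, path, progress = FALSE)
  } else {
    lt <- as.POSIXlt(df$timestamp, tz = "UTC")
    num <- function(v) ifelse(is.na(v), sfc_sentinel, v)
    lines <- sprintf("%4d %2d %2d %2d %8.4f %10.2f %8.1f %8.1f %8.4f %7.1f %7.2f %7.1f",
                     lt$year + 1900L, lt$mon + 1L, lt$mday, lt$hour + 1L,
                     num(df$ustar), num(df$L), num(df$zic), num(df$zim),
                     num(df$z0), num(df$wdir), num(df$u), num(df$temp_f))
    writeLines(lines, path)
  }
  invisible(path)
}
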