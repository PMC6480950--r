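#' Convert a mixing ratio in ppb to a mass concentration
#'
#' Converts a volume mixing ratio (parts per billion) to a mass concentration
#' in micrograms per cubic metre via \code{c * molar_mass / molar_volume}.
#' Defaults correspond to ozone (48.00 g/mol) at 25 degrees C and 1 atm
#' (molar volume 24.45 L/mol), the convention used by most regulatory
#' reporting.
#'
#' @param c mixing ratio in ppb; must be non-negative.
#' @param molar_mass molar mass of the gas in g/mol.
#' @param molar_volume molar volume in L/mol at the assumed temperature and
#'   pressure; must be positive.
#' @return mass concentration in ug/m3.
#' @seealso [mass_concentration_to_ppb()]
#' @examples
#' ppb_to_mass_concentration(27.96) # ~54.89 ug/m3 for ozone
#' @export
ppb_to_mass_concentration <- function(c, molar_mass = 48.00,
                                      molar_volume = 24.45) {
  if (!is.numeric(c) || any(!is.na(c) & c < 0)) {
    stopf("mixing ratio must be non-negative")
  }
  if (!is_scalar_number(molar_volume) || molar_volume <= 0) {
    stopf("molar_volume must be a positive number")
  }
  c * molar_mass / molar_volume
}

#' Convert a mass concentration to a mixing ratio in ppb
#'
#' Inverse of [ppb_to_mass_concentration()]; the two compose to the identity.
#'
#' @param x mass concentration in ug/m3; must be non-negative.
#' @inheritParams ppb_to_mass_concentration
#' @return mixing ratio in ppb.
#' @export
mass_concentration_to_ppb <- function(x, molar_mass = 48.00,
                                      molar_volume = 24.45) {
  if (!is.numeric(x) || any(!is.na(x) & x < 0)) {
    stopf("mass concentration must be non-negative")
  }
  if (!is_scalar_number(molar_volume) || molar_volume <= 0) {
    stopf("molar_volume must be a positive number")
  }
  x * molar_volume / molar_mass
}

STATION_CLASSES <- c("general", "traffic", "industrial", "national_park",
                     "background", "other")

STATION_COLUMNS <- c("station_id", "x", "y", "altitude", "station_class")

#' Validate a station table
#'
#' Checks the schema and invariants of a monitoring-station table: required
#' columns, unique station ids, finite planar coordinates (metres, projected
#' CRS), plausible altitude and a known station class.
#'
#' @param stations data frame with columns \code{station_id}, \code{x},
#'   \code{y}, \code{altitude}, \code{station_class}.
#' @return the validated data frame (invisibly classed as before).
#' @export
validate_stations <- function(stations) {
  missing_cols <- setdiff(STATION_COLUMNS, names(stations))
  if (length(missing_cols) > 0) {
    stopf("station table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  stations$station_id <- as.character(stations$station_id)
  dup <- unique(stations$station_id[duplicated(stations$station_id)])
  if (length(dup) > 0) {
    stopf("duplicate station_id(s): %s", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(stations$x)) || any(!is.finite(stations$y))) {
    stopf("station coordinates must be finite planar metres")
  }
  if (any(stations$altitude < -500 | stations$altitude > 9000)) {
    stopf("altitude out of range [-500, 9000] m")
  }
  bad <- setdiff(unique(stations$station_class), STATION_CLASSES)
  if (length(bad) > 0) {
    stopf("unknown station_class(es): %s", paste(bad, collapse = ", "))
  }
  stations
}

#' Read a station table from CSV
#'
#' @param path path to a UTF-8 CSV file with a header row containing
#'   \code{station_id}, \code{x}, \code{y} (planar metres), \code{altitude}
#'   (m a.s.l.) and \code{station_class}.
#' @return data frame of stations, validated by [validate_stations()].
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_stations(df)
}

#' Write a station table to CSV
#'
#' @param stations validated station data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stations <- function(stations, path) {
  stations <- validate_stations(stations)
  write.csv(stations[, STATION_COLUMNS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

DAILY_VARS <- c("o3", "nox", "co", "temperature", "relative_humidity", "uv")

#' Validate a daily-measurement table
#'
#' @param daily data frame with columns \code{station_id}, \code{date}
#'   (ISO-8601 or Date) and any of \code{o3}, \code{nox}, \code{co},
#'   \code{temperature}, \code{relative_humidity}, \code{uv}. Pollutant
#'   concentrations must be non-negative when present and relative humidity
#'   within [0, 100].
#' @return the validated data frame with `date` coerced to `Date`.
#' @export
validate_daily <- function(daily) {
  for (col in c("station_id", "date")) {
    if (!col %in% names(daily)) stopf("daily table is missing column: %s", col)
  }
  daily$station_id <- as.character(daily$station_id)
  daily$date <- as.Date(daily$date)
  if (any(is.na(daily$date))) stopf("unparseable date(s) in daily table")
  for (v in c("o3", "nox", "co")) {
    if (v %in% names(daily) && any(daily[[v]] < 0, na.rm = TRUE)) {
      stopf("negative %s concentration(s)", v)
    }
  }
  if ("relative_humidity" %in% names(daily)) {
    rh <- daily$relative_humidity
    if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
      stopf("relative_humidity outside [0, 100]")
    }
  }
  daily
}

days_in_period <- function(period) {
  # period is "YYYY" or "YYYY-MM"
  vapply(period, function(p) {
    if (nchar(p) == 4) {
      y <- as.integer(p)
      if ((y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0) 366L else 365L
    } else {
      y <- as.integer(substr(p, 1, 4))
      m <- as.integer(substr(p, 6, 7))
      first <- as.Date(sprintf("%04d-%02d-01", y, m))
      nxt <- if (m == 12) as.Date(sprintf("%04d-01-01", y + 1)) else
        as.Date(sprintf("%04d-%02d-01", y, m + 1))
      as.integer(nxt - first)
    }
  }, integer(1), USE.NAMES = FALSE)
}

#' Aggregate daily measurements to annual or monthly period means
#'
#' Computes per-(station, period) arithmetic means of each measured variable
#' over the days on which that variable is present. A row is retained only if
#' the fraction of days in the period with a valid ozone value is at least
#' `completeness` (default 0.75, the usual regulatory completeness
#' convention). The number of valid ozone days is recorded as
#' \code{n_valid_days}.
#'
#' @param daily validated daily-measurement data frame (see
#'   [validate_daily()]).
#' @param resolution `"annual"` or `"monthly"`.
#' @param completeness required valid-day fraction for ozone, in (0, 1].
#' @return data frame with columns \code{station_id}, \code{period},
#'   \code{year}, \code{mean_o3}, \code{mean_nox}, \code{mean_co},
#'   \code{mean_temperature}, \code{mean_rh}, \code{mean_uv},
#'   \code{n_valid_days}; one row per retained (station, period). Empty input
#'   yields an empty table.
#' @export
aggregate_to_periods <- function(daily, resolution = c("annual", "monthly"),
                                 completeness = 0.75) {
  resolution <- match.arg(resolution)
  if (!is_scalar_number(completeness) || completeness <= 0 ||
      completeness > 1) {
    stopf("completeness must be in (0, 1]")
  }
  out_cols <- c("station_id", "period", "year", "mean_o3", "mean_nox",
                "mean_co", "mean_temperature", "mean_rh", "mean_uv",
                "n_valid_days")
  empty <- as.data.frame(
    stats::setNames(
      list(character(), character(), integer(), numeric(), numeric(),
           numeric(), numeric(), numeric(), numeric(), integer()),
      out_cols
    )
  )
  if (nrow(daily) == 0) return(empty)
  daily <- validate_daily(daily)

  period <- if (resolution == "annual") {
    format(daily$date, "%Y")
  } else {
    format(daily$date, "%Y-%m")
  }
  key <- paste(daily$station_id, period, sep = "\r")
  groups <- split(seq_len(nrow(daily)), key)

  mean_of <- function(idx, v) {
    if (!v %in% names(daily)) return(NA_real_)
    x <- daily[[v]][idx]
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }

  rows <- lapply(groups, function(idx) {
    sid <- daily$station_id[idx[1]]
    per <- period[idx[1]]
    o3 <- if ("o3" %in% names(daily)) daily$o3[idx] else rep(NA_real_, length(idx))
    # one calendar day counts once even if duplicated in the input
    valid_days <- length(unique(daily$date[idx][!is.na(o3)]))
    data.frame(
      station_id = sid, period = per, year = as.integer(substr(per, 1, 4)),
      mean_o3 = mean_of(idx, "o3"), mean_nox = mean_of(idx, "nox"),
      mean_co = mean_of(idx, "co"),
      mean_temperature = mean_of(idx, "temperature"),
      mean_rh = mean_of(idx, "relative_humidity"),
      mean_uv = mean_of(idx, "uv"),
      n_valid_days = valid_days,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  keep <- out$n_valid_days / days_in_period(out$period) >= completeness
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$station_id, out$period), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) empty else out
}
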