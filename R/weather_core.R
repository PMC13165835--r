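# Ingestion, QC, daily aggregation and nearest-station gap-filling of
# heterogeneous station observations.

OBS_COLUMNS <- c(
  station_id = "station_id", timestamp = "timestamp", temp = "temp_c",
  rh = "rh_pct", precip = "precip_mm", wind_speed = "wind_ms",
  pressure = "pressure_hpa", co2 = "co2_ppm", uv = "uv_uw_cm2"
)

empty_obs <- function() {
  data.frame(
    station_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    temp = numeric(), rh = numeric(), precip = numeric(),
    wind_speed = numeric(), pressure = numeric(), co2 = numeric(),
    uv = numeric(), stringsAsFactors = FALSE
  )
}

#' Parse sub-daily station observations
#'
#' Reads 30-minute station observations from CSV or JSON. Expected keys are
#' `station_id`, `timestamp` (ISO-8601, interpreted as UTC), `temp_c`, and
#' optionally `rh_pct`, `precip_mm`, `wind_ms`, `pressure_hpa`, `co2_ppm`,
#' `uv_uw_cm2`. Rows that fail basic plausibility checks (unparseable
#' timestamp, relative humidity outside 0--100, negative precipitation,
#' non-numeric temperature) are excluded and collected in the attached
#' report rather than silently dropped; a missing required column is a hard
#' schema error.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`.
#' @return A data frame of observations sorted by (station_id, timestamp)
#'   with internal column names (`temp`, `rh`, `precip`, ...), carrying a
#'   `"report"` attribute: a data frame of excluded rows with the violated
#'   rule.
#' @export
parse_observations <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (format == "csv") {
    if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
      data.frame()
    } else {
      utils::read.csv(path, stringsAsFactors = FALSE)
    }
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("no observations in ", path, call. = FALSE)
    out <- empty_obs()
    attr(out, "report") <- data.frame(row = integer(), field = character(),
                                      issue = character())
    return(out)
  }
  required <- OBS_COLUMNS[c("station_id", "timestamp", "temp")]
  absent <- setdiff(unname(required), names(raw))
  if (length(absent) > 0) {
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  obs <- empty_obs()[seq_len(nrow(raw)), , drop = FALSE]
  rownames(obs) <- NULL
  for (internal in names(OBS_COLUMNS)) {
    ext <- OBS_COLUMNS[[internal]]
    if (ext %in% names(raw)) {
      val <- raw[[ext]]
      obs[[internal]] <- if (internal == "station_id") {
        as.character(val)
      } else if (internal == "timestamp") {
        as.POSIXct(val, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"),
                   optional = TRUE)
      } else {
        suppressWarnings(as.numeric(val))
      }
    }
  }

  issues <- list()
  flag <- function(bad, field, issue) {
    bad <- which(bad)
    if (length(bad) > 0) {
      issues[[length(issues) + 1L]] <<- data.frame(
        row = bad, field = field, issue = issue, stringsAsFactors = FALSE)
    }
    bad
  }
  drop <- unique(c(
    flag(is.na(obs$timestamp), "timestamp", "unparseable timestamp"),
    flag(is.na(obs$temp), "temp", "non-numeric or missing temperature"),
    flag(!is.na(obs$rh) & (obs$rh < 0 | obs$rh > 100), "rh",
         "relative humidity outside [0, 100]"),
    flag(!is.na(obs$precip) & obs$precip < 0, "precip",
         "negative precipitation")
  ))
  report <- if (length(issues) > 0) do.call(rbind, issues) else
    data.frame(row = integer(), field = character(), issue = character())
  if (length(drop) > 0) obs <- obs[-drop, , drop = FALSE]
  obs <- obs[order(obs$station_id, obs$timestamp), , drop = FALSE]
  rownames(obs) <- NULL
  attr(obs, "report") <- report[order(report$row), , drop = FALSE]
  obs
}

#' Quality-control report for sub-daily observations
#'
#' Checks each variable against plausible ranges and each station stream for
#' duplicate or non-monotonic timestamps. The input is never mutated; the
#' result is a report only.
#'
#' @param obs Observation data frame (see [parse_observations()]).
#' @param limits Named list of `c(min, max)` plausible ranges per variable;
#'   see [qc_limits()] for the defaults.
#' @return Data frame with columns station_id, timestamp, field, value,
#'   issue (zero rows for a clean stream).
#' @export
qc_validate <- function(obs, limits = qc_limits()) {
  out <- list()
  add <- function(idx, field, value, issue) {
    if (length(idx) > 0) {
      out[[length(out) + 1L]] <<- data.frame(
        station_id = obs$station_id[idx], timestamp = obs$timestamp[idx],
        field = field, value = value, issue = issue, stringsAsFactors = FALSE)
    }
  }
  for (field in names(limits)) {
    if (!field %in% names(obs)) next
    v <- obs[[field]]
    bad <- which(!is.na(v) & (v < limits[[field]][1] | v > limits[[field]][2]))
    add(bad, field, v[bad], sprintf("outside plausible range [%g, %g]",
                                    limits[[field]][1], limits[[field]][2]))
  }
  for (sid in unique(obs$station_id)) {
    idx <- which(obs$station_id == sid)
    ts <- obs$timestamp[idx]
    dup <- idx[duplicated(ts)]
    add(dup, "timestamp", as.numeric(obs$timestamp[dup]),
        "duplicate timestamp")
    if (length(ts) > 1) {
      non_mono <- idx[-1][diff(as.numeric(ts)) < 0]
      add(non_mono, "timestamp", as.numeric(obs$timestamp[non_mono]),
          "non-monotonic timestamp")
    }
  }
  if (length(out) == 0) {
    return(data.frame(station_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      field = character(), value = numeric(),
                      issue = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default QC plausibility limits
#'
#' Ranges broad enough for Mediterranean station data: temperature -30 to
#' 50 degC, relative humidity 0--100 %, per-interval precipitation 0--100 mm,
#' wind 0--60 m/s, pressure 850--1100 hPa.
#'
#' @return Named list of `c(min, max)` per variable.
#' @export
qc_limits <- function() {
  list(temp = c(-30, 50), rh = c(0, 100), precip = c(0, 100),
       wind_speed = c(0, 60), pressure = c(850, 1100))
}

#' Aggregate sub-daily observations to daily weather
#'
#' Collapses a single station (or pre-merged site) stream to UTC calendar
#' days: tmin/tmax/tmean from the temperature samples, precipitation summed,
#' relative humidity averaged. A day with fewer temperature samples than
#' `completeness * expected_samples` is flagged incomplete (its aggregates
#' are still reported, but gap-filling treats it as a gap); a day with no
#' temperature samples at all is never fabricated and simply does not appear.
#'
#' @param obs Observation data frame.
#' @param site_id Site identifier stamped on the output.
#' @param expected_samples Nominal samples per day (48 at the 30-min cadence).
#' @param completeness Minimum fraction of expected samples for a complete
#'   day (default 0.8, i.e. at least 39 of 48).
#' @param source Provenance label for the aggregated days.
#' @return Daily weather data frame: site_id, date, tmin, tmax, tmean,
#'   precip, rh_mean, source, fill_station, fill_distance_km, complete.
#' @export
aggregate_daily <- function(obs, site_id, expected_samples = 48L,
                            completeness = 0.8, source = "iot") {
  if (nrow(obs) == 0L) return(empty_daily())
  date <- as.Date(obs$timestamp, tz = "UTC")
  split_idx <- split(seq_len(nrow(obs)), date)
  rows <- lapply(names(split_idx), function(d) {
    i <- split_idx[[d]]
    temp <- obs$temp[i]
    temp <- temp[!is.na(temp)]
    if (length(temp) == 0L) return(NULL)  # never fabricate a day
    rh <- obs$rh[i]
    data.frame(
      site_id = site_id, date = as.Date(d),
      tmin = min(temp), tmax = max(temp), tmean = mean(temp),
      precip = sum(obs$precip[i], na.rm = TRUE),
      rh_mean = if (all(is.na(rh))) NA_real_ else mean(rh, na.rm = TRUE),
      source = source, fill_station = NA_character_,
      fill_distance_km = NA_real_,
      complete = length(temp) >= completeness * expected_samples,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_daily())
  out <- do.call(rbind, rows)
  out[order(out$date), , drop = FALSE]
}

empty_daily <- function() {
  data.frame(
    site_id = character(), date = as.Date(character()), tmin = numeric(),
    tmax = numeric(), tmean = numeric(), precip = numeric(),
    rh_mean = numeric(), source = character(), fill_station = character(),
    fill_distance_km = numeric(), complete = logical(),
    stringsAsFactors = FALSE
  )
}

#' Build a station network
#'
#' @param stations Data frame with columns station_id, lat, lon,
#'   elevation_m, kind (`"iot"` or `"national"`), status (`"online"` or
#'   `"offline"`).
#' @param series Named list (by station_id) of daily weather data frames.
#' @return An object of class `station_network`.
#' @export
station_network <- function(stations, series = list()) {
  stopifnot(is.data.frame(stations),
            all(c("station_id", "lat", "lon", "kind", "status") %in%
                  names(stations)))
  if (anyDuplicated(stations$station_id)) {
    stop("duplicate station_id in network", call. = FALSE)
  }
  if (any(stations$lat < -90 | stations$lat > 90) ||
      any(stations$lon < -180 | stations$lon > 180)) {
    stop("station coordinates out of range", call. = FALSE)
  }
  unknown <- setdiff(names(series), stations$station_id)
  if (length(unknown) > 0) {
    stop("series for unregistered station(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(stations = stations, series = series),
            class = "station_network")
}

#' Read a station registry CSV
#'
#' Columns: station_id, lat, lon, elevation_m, kind, status.
#' @param path CSV file.
#' @return Station data frame suitable for [station_network()].
#' @export
read_station_registry <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("station_id", "lat", "lon", "kind", "status")
  absent <- setdiff(needed, names(st))
  if (length(absent) > 0) {
    stop("station registry missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  st$station_id <- as.character(st$station_id)
  st
}

#' Nearest station to a point
#'
#' Great-circle (haversine) nearest eligible station. Ties between
#' equidistant stations are broken by lexicographic station_id.
#'
#' @param lat,lon Query point, decimal degrees.
#' @param network A [station_network()].
#' @param require_online Only consider stations with status `"online"`.
#' @param kind Optionally restrict to `"iot"` or `"national"` stations.
#' @param exclude Station ids to ignore (e.g. the site's own station).
#' @return List with elements `station` (one-row data frame) and
#'   `distance_km`.
#' @export
nearest_station <- function(lat, lon, network, require_online = FALSE,
                            kind = NULL, exclude = NULL) {
  st <- network$stations
  if (require_online) st <- st[st$status == "online", , drop = FALSE]
  if (!is.null(kind)) st <- st[st$kind %in% kind, , drop = FALSE]
  if (!is.null(exclude)) st <- st[!st$station_id %in% exclude, , drop = FALSE]
  if (nrow(st) == 0L) stop("no station available", call. = FALSE)
  d <- haversine_km(lat, lon, st$lat, st$lon)
  ord <- order(d, st$station_id)
  list(station = st[ord[1], , drop = FALSE], distance_km = d[ord[1]])
}

#' Fill gaps in a daily series from the nearest national station
#'
#' Missing or incomplete days are replaced by the same-date record of the
#' nearest national station that has a complete record for that day; each
#' substituted day carries `source = "gap_filled"` together with the donor
#' station id and its distance from the site. Whole daily records are
#' substituted (never per-variable blends) so provenance stays simple. Days
#' no donor can provide remain missing. The operation is idempotent.
#'
#' @param site_series Daily weather data frame for the site.
#' @param site_meta One-row data frame (or list) with the site's lat/lon and
#'   station_id.
#' @param network A [station_network()] whose `series` hold donor daily data.
#' @param dates Optional vector of dates the output should cover; defaults
#'   to the span of `site_series`.
#' @return Daily weather data frame sorted by date, with attribute
#'   `"fill_report"`: list(n_filled, n_unfilled, unfilled_dates).
#' @export
fill_gaps <- function(site_series, site_meta, network, dates = NULL) {
  if (is.null(dates)) {
    if (nrow(site_series) == 0L) stop("empty site series and no dates given",
                                      call. = FALSE)
    dates <- seq(min(site_series$date), max(site_series$date), by = "day")
  }
  ok <- site_series[site_series$complete %in% TRUE |
                      site_series$source == "gap_filled", , drop = FALSE]
  need <- as.Date(setdiff(dates, ok$date), origin = "1970-01-01")

  donors <- network$stations[network$stations$kind == "national", ,
                             drop = FALSE]
  if (nrow(donors) > 0) {
    d <- haversine_km(site_meta$lat, site_meta$lon, donors$lat, donors$lon)
    ord <- order(d, donors$station_id)
    donors <- donors[ord, , drop = FALSE]
    donors$distance_km <- d[ord]
  }

  filled <- list()
  unfilled <- as.Date(character())
  for (day in as.list(need)) {
    hit <- NULL
    for (j in seq_len(nrow(donors))) {
      ds <- network$series[[donors$station_id[j]]]
      if (is.null(ds)) next
      row <- ds[ds$date == day & ds$complete %in% TRUE, , drop = FALSE]
      if (nrow(row) == 1L) {
        row$site_id <- if (nrow(site_series) > 0) site_series$site_id[1] else
          site_meta$station_id
        row$source <- "gap_filled"
        row$fill_station <- donors$station_id[j]
        row$fill_distance_km <- donors$distance_km[j]
        hit <- row
        break
      }
    }
    if (is.null(hit)) unfilled <- c(unfilled, day) else
      filled[[length(filled) + 1L]] <- hit
  }
  out <- rbind(ok, if (length(filled) > 0) do.call(rbind, filled))
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fill_report") <- list(n_filled = length(filled),
                                   n_unfilled = length(unfilled),
                                   unfilled_dates = unfilled)
  out
}

#' Write / read the daily weather CSV schema
#'
#' Columns: site_id, date, tmin_c, tmax_c, tmean_c, precip_mm, rh_mean_pct,
#' source, fill_station, fill_distance_km.
#' @param daily Daily weather data frame.
#' @param path Output CSV path.
#' @export
write_daily_csv <- function(daily, path) {
  out <- data.frame(
    site_id = daily$site_id, date = format(daily$date),
    tmin_c = daily$tmin, tmax_c = daily$tmax, tmean_c = daily$tmean,
    precip_mm = daily$precip, rh_mean_pct = daily$rh_mean,
    source = daily$source, fill_station = daily$fill_station,
    fill_distance_km = daily$fill_distance_km, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_daily_csv
#' @export
read_daily_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    site_id = as.character(raw$site_id), date = as.Date(raw$date),
    tmin = raw$tmin_c, tmax = raw$tmax_c, tmean = raw$tmean_c,
    precip = raw$precip_mm,
    rh_mean = if ("rh_mean_pct" %in% names(raw)) raw$rh_mean_pct else NA_real_,
    source = if ("source" %in% names(raw)) as.character(raw$source) else "iot",
    fill_station = if ("fill_station" %in% names(raw))
      as.character(raw$fill_station) else NA_character_,
    fill_distance_km = if ("fill_distance_km" %in% names(raw))
      raw$fill_distance_km else NA_real_,
    complete = TRUE, stringsAsFactors = FALSE
  )
}
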