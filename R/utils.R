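# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

days_in_month <- function(year, month) {
  dim <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- dim[month]
  out[month == 2L & is_leap_year(year)] <- 29L
  out
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @param radius_km Sphere radius in km.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

# Assert a daily series is contiguous; returns sorted series or stops naming
# the first missing date.
check_contiguous <- function(daily, what = "daily series") {
  daily <- daily[order(daily$date), , drop = FALSE]
  if (nrow(daily) > 1) {
    full <- seq(min(daily$date), max(daily$date), by = "day")
    missing <- full[!full %in% daily$date]
    if (length(missing) > 0) {
      stop(sprintf("gap in %s: first missing date %s (%d missing in total)",
                   what, format(missing[1]), length(missing)), call. = FALSE)
    }
  }
  daily
}

# Require a window of dates to be fully covered; stops listing missing dates.
check_window_coverage <- function(daily, start, end, what = "window") {
  wanted <- seq(as.Date(start), as.Date(end), by = "day")
  missing <- wanted[!wanted %in% daily$date]
  if (length(missing) > 0) {
    shown <- paste(format(utils::head(missing, 5)), collapse = ", ")
    stop(sprintf("%d missing day(s) in %s: %s%s", length(missing), what,
                 shown, if (length(missing) > 5) ", ..." else ""),
         call. = FALSE)
  }
  daily[daily$date %in% wanted, , drop = FALSE]
}
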