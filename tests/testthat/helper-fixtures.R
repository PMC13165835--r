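# Fixtures built in code; no stored data.

# One civil year of constant weather.
constant_year <- function(year = 2025, tmean = 20, tmin = 15, tmax = 25,
                          precip = 2, rh = 70, site_id = "site-1") {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  data.frame(site_id = site_id, date = dates, tmin = tmin, tmax = tmax,
             tmean = tmean, precip = precip, rh_mean = rh, source = "iot",
             fill_station = NA_character_, fill_distance_km = NA_real_,
             complete = TRUE, stringsAsFactors = FALSE)
}

# Single-cell increment table giving a flat daily increment.
toy_table <- function(inc = 5, tmax_bin = 50, rhmax_bin = 100) {
  increment_table(c(-50, tmax_bin), c(0, rhmax_bin),
                  matrix(inc, 1, 1))
}

# Small two-station network with daily series attached to the donors.
toy_network <- function(donor_daily = NULL) {
  stations <- data.frame(
    station_id = c("iot-1", "nat-1", "nat-2"),
    lat = c(42.4, 42.5, 43.0), lon = c(19.2, 19.3, 19.0),
    elevation_m = c(50, 40, 600),
    kind = c("iot", "national", "national"),
    status = c("online", "online", "online"),
    stringsAsFactors = FALSE)
  series <- list()
  if (!is.null(donor_daily)) series[["nat-1"]] <- donor_daily
  station_network(stations, series)
}

write_obs_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
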