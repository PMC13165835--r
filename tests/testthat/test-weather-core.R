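test_that("parse_observations keeps valid rows and reports malformed ones", {
  f <- tempfile(fileext = ".csv")
  write_obs_csv(data.frame(
    station_id = "s1",
    timestamp = c("2025-05-01T00:00:00", "2025-05-01T00:30:00",
                  "2025-05-01T01:00:00"),
    temp_c = c(12, 12.5, 13), rh_pct = c(60, 120, 65),
    precip_mm = c(0, 0, 0.2)), f)
  obs <- parse_observations(f, "csv")
  expect_equal(nrow(obs), 2L)
  report <- attr(obs, "report")
  expect_equal(nrow(report), 1L)
  expect_match(report$issue, "relative humidity")

  # missing required column is a schema error, not a row report
  f2 <- tempfile(fileext = ".csv")
  write_obs_csv(data.frame(station_id = "s1", temp_c = 10), f2)
  expect_error(parse_observations(f2, "csv"), "required column")
})

test_that("an empty file parses to an empty collection with a warning", {
  f <- tempfile(fileext = ".csv")
  file.create(f)
  expect_warning(obs <- parse_observations(f, "csv"), "no observations")
  expect_equal(nrow(obs), 0L)
})

test_that("JSON ingestion preserves the 48-sample 30-minute cadence", {
  day <- constant_year()[121, ]
  sub <- disaggregate_subdaily(day)
  f <- tempfile(fileext = ".json")
  payload <- data.frame(station_id = sub$station_id,
                        timestamp = format(sub$timestamp,
                                           "%Y-%m-%dT%H:%M:%S"),
                        temp_c = sub$temp, rh_pct = sub$rh,
                        precip_mm = sub$precip)
  jsonlite::write_json(payload, f, dataframe = "rows")
  obs <- parse_observations(f, "json")
  expect_equal(nrow(obs), 48L)
  expect_true(all(diff(as.numeric(obs$timestamp)) == 1800))
})

test_that("daily aggregation reproduces direct arithmetic", {
  day <- as.POSIXct("2025-06-01 00:00:00", tz = "UTC")
  obs <- data.frame(
    station_id = "s1", timestamp = day + (0:47) * 1800,
    temp = rep(c(10, 20), 24), rh = 70, precip = 0.5,
    wind_speed = NA_real_, pressure = NA_real_, co2 = NA_real_,
    uv = NA_real_, stringsAsFactors = FALSE)
  d <- aggregate_daily(obs, "s1")
  expect_equal(d$tmin, 10)
  expect_equal(d$tmax, 20)
  expect_equal(d$tmean, 15)
  expect_equal(d$precip, 24)
  expect_true(d$complete)

  constant <- obs
  constant$temp <- 10
  dc <- aggregate_daily(constant, "s1")
  expect_equal(c(dc$tmin, dc$tmax, dc$tmean), c(10, 10, 10))

  # dropout below the 80% completeness threshold flags the day
  short <- obs[1:10, ]
  ds <- aggregate_daily(short, "s1")
  expect_false(ds$complete)
})

test_that("aggregation is permutation-invariant and ordered", {
  day <- as.POSIXct("2025-06-01 00:00:00", tz = "UTC")
  obs <- data.frame(
    station_id = "s1", timestamp = day + (0:95) * 1800,
    temp = stats::rnorm(96, 15, 5), rh = stats::runif(96, 40, 90),
    precip = stats::rexp(96, 2), wind_speed = NA_real_,
    pressure = NA_real_, co2 = NA_real_, uv = NA_real_,
    stringsAsFactors = FALSE)
  shuffled <- obs[sample.int(nrow(obs)), ]
  expect_equal(aggregate_daily(shuffled, "s1"), aggregate_daily(obs, "s1"))
})

test_that("tmin <= tmean <= tmax holds on fuzzed streams", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:96, 1)
    obs <- data.frame(
      station_id = "s1",
      timestamp = as.POSIXct("2025-06-01", tz = "UTC") +
        sort(sample.int(48 * 3600, n)),
      temp = stats::rnorm(n, 15, 10), rh = stats::runif(n, 0, 100),
      precip = stats::rexp(n, 1), wind_speed = NA_real_,
      pressure = NA_real_, co2 = NA_real_, uv = NA_real_,
      stringsAsFactors = FALSE)
    d <- aggregate_daily(obs, "s1")
    expect_true(all(d$tmin <= d$tmean & d$tmean <= d$tmax))
  }
})

test_that("haversine distance matches independent oracles", {
  # spherical law of cosines, written here independently of the package
  slc_km <- function(lat1, lon1, lat2, lon2, r = 6371.0088) {
    to_rad <- pi / 180
    r * acos(pmin(1, sin(lat1 * to_rad) * sin(lat2 * to_rad) +
                    cos(lat1 * to_rad) * cos(lat2 * to_rad) *
                      cos((lon2 - lon1) * to_rad)))
  }
  set.seed(7)
  lat1 <- stats::runif(100, -60, 60); lon1 <- stats::runif(100, -180, 180)
  lat2 <- lat1 + stats::runif(100, 0.05, 5)
  lon2 <- lon1 + stats::runif(100, 0.05, 5)
  h <- haversine_km(lat1, lon1, lat2, lon2)
  s <- slc_km(lat1, lon1, lat2, lon2)
  expect_true(all(abs(h - s) / s < 0.005))
  expect_equal(haversine_km(42.4, 19.2, 42.4, 19.2), 0)
  expect_equal(haversine_km(42.4, 19.2, 43.1, 18.7),
               haversine_km(43.1, 18.7, 42.4, 19.2))
  skip_if_not_installed("geosphere")
  g <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                r = 6371008.8) / 1000
  expect_equal(h, g, tolerance = 1e-6)
})

test_that("nearest_station picks the great-circle nearest eligible station", {
  net <- station_network(data.frame(
    station_id = c("a", "b"), lat = c(0, 0), lon = c(0, 1),
    elevation_m = 0, kind = "national", status = c("offline", "offline"),
    stringsAsFactors = FALSE))
  hit <- nearest_station(0, 0.4, net)
  expect_equal(hit$station$station_id, "a")
  expect_equal(hit$distance_km, 44.5, tolerance = 0.01)

  self <- nearest_station(0, 1, net)
  expect_equal(self$station$station_id, "b")
  expect_equal(self$distance_km, 0)

  expect_error(nearest_station(0, 0, net, require_online = TRUE),
               "no station available")

  # equidistant tie breaks lexicographically
  tie <- station_network(data.frame(
    station_id = c("zz", "aa"), lat = c(0, 0), lon = c(-1, 1),
    elevation_m = 0, kind = "national", status = "online",
    stringsAsFactors = FALSE))
  expect_equal(nearest_station(0, 0, tie)$station$station_id, "aa")
})

test_that("fill_gaps substitutes whole days from the nearest national donor", {
  donor <- constant_year(site_id = "nat-1")
  donor$source <- "national"
  net <- toy_network(donor)
  meta <- net$stations[net$stations$station_id == "iot-1", ]

  full <- constant_year(site_id = "iot-1")
  expect_equal(fill_gaps(full, meta, net), full, ignore_attr = TRUE)
  expect_true(all(fill_gaps(full, meta, net)$source == "iot"))

  gappy <- full[-100, ]
  filled <- fill_gaps(gappy, meta, net)
  expect_equal(nrow(filled), 365L)
  day <- filled[filled$date == full$date[100], ]
  expect_equal(day$source, "gap_filled")
  expect_equal(day$fill_station, "nat-1")
  expect_equal(day$fill_distance_km,
               haversine_km(42.4, 19.2, 42.5, 19.3))

  # idempotence
  expect_equal(fill_gaps(filled, meta, net), filled, ignore_attr = TRUE)

  # a day no donor has stays missing and is counted
  donor_short <- donor[-100, ]
  net2 <- toy_network(donor_short)
  unfilled <- fill_gaps(gappy, meta, net2)
  expect_equal(nrow(unfilled), 364L)
  expect_equal(attr(unfilled, "fill_report")$n_unfilled, 1L)
})

test_that("qc_validate reports violations without mutating input", {
  day <- as.POSIXct("2025-06-01 00:00:00", tz = "UTC")
  obs <- data.frame(
    station_id = "s1", timestamp = day + c(0, 1800, 1800, 900) ,
    temp = c(12, -80, 13, 14), rh = 70, precip = 0,
    wind_speed = NA_real_, pressure = NA_real_, co2 = NA_real_,
    uv = NA_real_, stringsAsFactors = FALSE)
  rep <- qc_validate(obs)
  expect_true(any(rep$issue == "duplicate timestamp"))
  expect_true(any(grepl("plausible range", rep$issue) & rep$field == "temp"))
  expect_true(any(rep$issue == "non-monotonic timestamp"))

  clean <- obs[c(1, 3), ]
  clean$timestamp <- day + c(0, 1800)
  expect_equal(nrow(qc_validate(clean)), 0L)
})
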