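# Seeded stochastic weather generator: sinusoidal annual cycle with AR(1)
# temperature noise, two-state Markov precipitation occurrence with
# Gamma-distributed wet-day amounts, and a diurnal disaggregator. Exists so
# every downstream engine is testable without external data.

#' Weather generator parameters
#'
#' Defaults emulate a Podgorica-like Mediterranean regime: annual mean
#' 15 degC with a 10 degC seasonal amplitude peaking in late July, a 10 degC
#' diurnal range, moderately persistent day-to-day anomalies, about 120-130
#' wet days per year with Gamma-distributed amounts (mean ~11 mm/wet day).
#' These defaults are test fixtures for a realistic regime, not site claims.
#'
#' @param lat Site latitude, decimal degrees.
#' @param t_annual_mean Annual mean temperature, degC.
#' @param t_annual_amplitude Seasonal half-range of the sinusoid, degC.
#' @param t_diurnal_range tmax - tmin, degC.
#' @param t_noise_sd Marginal standard deviation of the AR(1) anomaly, degC.
#' @param t_ar1 Lag-1 autocorrelation of the anomaly, in [0, 1).
#' @param p_wet_given_wet,p_wet_given_dry Markov-chain transition
#'   probabilities for precipitation occurrence.
#' @param precip_gamma_shape,precip_gamma_scale Gamma parameters for wet-day
#'   amounts (scale in mm).
#' @param rh_base Baseline relative humidity, %.
#' @param seed Integer seed governing all stochastic draws.
#' @return List of class `weather_gen_params`.
#' @export
weather_gen_params <- function(lat = 42.44, t_annual_mean = 15,
                               t_annual_amplitude = 10, t_diurnal_range = 10,
                               t_noise_sd = 2, t_ar1 = 0.7,
                               p_wet_given_wet = 0.55, p_wet_given_dry = 0.25,
                               precip_gamma_shape = 0.9,
                               precip_gamma_scale = 12, rh_base = 65,
                               seed = 1L) {
  stopifnot(t_annual_amplitude > 0, t_diurnal_range > 0, t_noise_sd >= 0,
            t_ar1 >= 0, t_ar1 < 1,
            p_wet_given_wet >= 0, p_wet_given_wet <= 1,
            p_wet_given_dry >= 0, p_wet_given_dry <= 1,
            precip_gamma_shape > 0, precip_gamma_scale > 0)
  structure(
    list(lat = lat, t_annual_mean = t_annual_mean,
         t_annual_amplitude = t_annual_amplitude,
         t_diurnal_range = t_diurnal_range, t_noise_sd = t_noise_sd,
         t_ar1 = t_ar1, p_wet_given_wet = p_wet_given_wet,
         p_wet_given_dry = p_wet_given_dry,
         precip_gamma_shape = precip_gamma_shape,
         precip_gamma_scale = precip_gamma_scale, rh_base = rh_base,
         seed = as.integer(seed)),
    class = "weather_gen_params")
}

# Run expr under a locally seeded RNG stream without disturbing the
# caller's .Random.seed. `offset` gives each module its own substream.
with_local_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  expr
}

#' Generate synthetic daily weather
#'
#' Daily mean temperature follows a sinusoid peaking on day-of-year 205
#' (late July) plus a stationary AR(1) anomaly; tmax/tmin sit half the
#' diurnal range above/below tmean. Wet/dry occurrence follows a two-state
#' Markov chain started from its stationary probability, wet-day amounts are
#' Gamma draws, and relative humidity is a clamped linear response to the
#' temperature anomaly plus a wet-day bonus. Identical seeds give identical
#' output.
#'
#' @param params A [weather_gen_params()] object.
#' @param start_year First calendar year.
#' @param n_years Number of years (>= 1).
#' @param site_id Identifier stamped on the series.
#' @return Daily weather data frame (schema of [aggregate_daily()]) with
#'   `source = "synthetic"`.
#' @export
generate_daily_weather <- function(params, start_year, n_years,
                                   site_id = "synthetic-site") {
  stopifnot(inherits(params, "weather_gen_params"), n_years >= 1)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- params$t_annual_mean +
    params$t_annual_amplitude * cos(2 * pi * (doy - 205) / 365)

  sim <- with_local_seed(params$seed, 0L, {
    z <- stats::rnorm(n)
    u <- stats::runif(n)
    amt <- stats::rgamma(n, shape = params$precip_gamma_shape,
                         scale = params$precip_gamma_scale)
    list(z = z, u = u, amt = amt)
  })

  # stationary-start AR(1): e_1 ~ N(0, sd^2), innovations scaled so the
  # marginal sd stays t_noise_sd
  e <- numeric(n)
  e[1] <- params$t_noise_sd * sim$z[1]
  if (n > 1) {
    innov_sd <- params$t_noise_sd * sqrt(1 - params$t_ar1^2)
    for (t in 2:n) e[t] <- params$t_ar1 * e[t - 1] + innov_sd * sim$z[t]
  }

  p_ww <- params$p_wet_given_wet
  p_wd <- params$p_wet_given_dry
  denom <- 1 - p_ww + p_wd
  pi_wet <- if (denom <= 0) 1 else p_wd / denom  # stationary wet probability
  wet <- logical(n)
  wet[1] <- sim$u[1] < pi_wet
  if (n > 1) {
    for (t in 2:n) wet[t] <- sim$u[t] < (if (wet[t - 1]) p_ww else p_wd)
  }
  precip <- ifelse(wet, sim$amt, 0)

  tmean <- seasonal + e
  rh <- clamp(params$rh_base - 0.5 * (tmean - params$t_annual_mean) +
                10 * wet, 5, 100)
  data.frame(
    site_id = site_id, date = dates, tmin = tmean - params$t_diurnal_range / 2,
    tmax = tmean + params$t_diurnal_range / 2, tmean = tmean,
    precip = precip, rh_mean = rh, source = "synthetic",
    fill_station = NA_character_, fill_distance_km = NA_real_,
    complete = TRUE, stringsAsFactors = FALSE
  )
}

#' Disaggregate daily weather to 30-minute observations
#'
#' Produces the 48 half-hourly records of each day. Temperature follows a
#' continuous diurnal curve with its minimum at 06:00 and maximum at 15:00
#' (sine rise, cosine fall); per-interval precipitation is a telescoping
#' split of the daily total, so re-accumulation is exact; relative humidity
#' is held at the daily mean.
#'
#' @param daily Daily weather data frame (one or more complete days).
#' @param params A [weather_gen_params()] (unused stochastic fields are
#'   ignored; present for interface symmetry).
#' @return Sub-daily observation data frame (48 rows per day).
#' @export
disaggregate_subdaily <- function(daily, params = weather_gen_params()) {
  hours <- seq(0, 23.5, by = 0.5)
  out <- lapply(seq_len(nrow(daily)), function(i) {
    d <- daily[i, ]
    mid <- (d$tmin + d$tmax) / 2
    amp <- (d$tmax - d$tmin) / 2
    h <- hours
    temp <- ifelse(
      h >= 6 & h <= 15,
      mid + amp * sin(pi * (h - 6) / 9 - pi / 2),
      {
        hh <- ifelse(h < 6, h + 24, h)  # evening/night branch: 15:00 -> 30:00
        mid + amp * cos(pi * (hh - 15) / 15)
      })
    cum <- d$precip * seq_along(h) / length(h)
    precip <- diff(c(0, cum))  # sums to d$precip exactly (telescoping)
    data.frame(
      station_id = d$site_id,
      timestamp = as.POSIXct(paste(format(d$date), "00:00:00"),
                             tz = "UTC") + h * 3600,
      temp = temp, rh = rep(d$rh_mean, length(h)), precip = precip,
      wind_speed = NA_real_, pressure = NA_real_, co2 = NA_real_,
      uv = NA_real_, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inject contiguous observation gaps
#'
#' Removes contiguous runs of records (geometric run lengths with the given
#' mean) until the requested fraction is missing; the final run is trimmed
#' so the realized fraction matches the target to within one record. Seeded
#' and reproducible.
#'
#' @param obs Sub-daily observation data frame.
#' @param gap_fraction Target missing fraction in [0, 1].
#' @param mean_gap_len Mean run length, records.
#' @param seed Integer seed.
#' @return The observations with gap runs removed.
#' @export
inject_gaps <- function(obs, gap_fraction, mean_gap_len = 8, seed = 1L) {
  stopifnot(gap_fraction >= 0, gap_fraction <= 1, mean_gap_len >= 1)
  n <- nrow(obs)
  if (gap_fraction == 0 || n == 0L) return(obs)
  if (gap_fraction == 1) return(obs[0, , drop = FALSE])
  target <- round(n * gap_fraction)
  if (target == 0L) return(obs)
  drop <- with_local_seed(seed, 101L, {
    gone <- logical(n)
    guard <- 0L
    while (sum(gone) < target && guard < 10L * n) {
      guard <- guard + 1L
      start <- sample.int(n, 1L)
      len <- 1L + stats::rgeom(1L, 1 / mean_gap_len)
      idx <- start:min(n, start + len - 1L)
      idx <- idx[!gone[idx]]
      excess <- (sum(gone) + length(idx)) - target
      if (excess > 0) idx <- utils::head(idx, length(idx) - excess)
      gone[idx] <- TRUE
    }
    gone
  })
  obs[!drop, , drop = FALSE]
}

#' Load weather generator parameters from YAML
#'
#' Any subset of the [weather_gen_params()] arguments may be given; the
#' rest keep their defaults.
#'
#' @param path YAML file.
#' @return A [weather_gen_params()].
#' @export
load_weather_gen_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(weather_gen_params))
  do.call(weather_gen_params, cfg[intersect(names(cfg), known)])
}
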