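# Recursive daily soil-water-balance Dryness Index (DI) with Thornthwaite
# potential evapotranspiration and threshold-based irrigation alerts.
#
# Daily balance: DI_t = min(cap, DI_{t-1} + P_t - Tv - Es) with vine
# transpiration Tv = k1 * ETP_t and soil evaporation
# Es = (1 - k1) * ETP_t * min(P_t / 5, 1): bare-soil evaporation only acts
# when rain has wetted the surface. k1 is a seasonal crop coefficient.

#' Dryness Index parameters
#'
#' @param w0 Initial soil water reserve, mm (200 mm default).
#' @param cap Upper bound of the reserve, mm (200 mm).
#' @param alert_threshold Operational alert level, mm (50 mm); days with
#'   DI strictly below it are flagged.
#' @param k1_schedule Numeric vector of 12 monthly crop coefficients in
#'   [0, 1]. Default follows the Riou/Tonietto dryness-index convention:
#'   0.1 in April, 0.3 in May, 0.5 June--September, 0.1 otherwise.
#' @param es_rain_scale Rain depth (mm) at which the soil-evaporation
#'   wetting factor min(P/scale, 1) saturates; 5 mm default.
#' @return List of class `dryness_params`.
#' @export
dryness_params <- function(w0 = 200, cap = 200, alert_threshold = 50,
                           k1_schedule = default_k1_schedule(),
                           es_rain_scale = 5) {
  stopifnot(w0 > 0, w0 <= cap, alert_threshold < cap,
            length(k1_schedule) == 12L,
            all(k1_schedule >= 0), all(k1_schedule <= 1), es_rain_scale > 0)
  structure(list(w0 = w0, cap = cap, alert_threshold = alert_threshold,
                 k1_schedule = k1_schedule, es_rain_scale = es_rain_scale),
            class = "dryness_params")
}

#' @rdname dryness_params
#' @export
default_k1_schedule <- function() {
  c(0.1, 0.1, 0.1, 0.1, 0.3, 0.5, 0.5, 0.5, 0.5, 0.1, 0.1, 0.1)
}

#' Thornthwaite annual heat index
#'
#' I = sum over months of (max(0, T_m) / 5)^1.514; months at or below 0 degC
#' contribute nothing.
#'
#' @param monthly_tmean Twelve monthly mean temperatures, degC.
#' @return Dimensionless heat index.
#' @export
annual_heat_index <- function(monthly_tmean) {
  stopifnot(length(monthly_tmean) == 12L)
  sum((pmax(0, monthly_tmean) / 5)^1.514)
}

#' Photoperiod (astronomical day length)
#'
#' L = (24/pi) * acos(-tan(lat) * tan(delta)) hours, with solar declination
#' delta = 0.409 * sin(2*pi*doy/365 - 1.39) radians.
#'
#' @param lat Latitude, decimal degrees; |lat| must be below 66.5 (no
#'   polar day/night support).
#' @param doy Day of year (1--366).
#' @return Day length in hours (vectorised over `doy`).
#' @export
photoperiod <- function(lat, doy) {
  if (abs(lat) >= 66.5) {
    stop("polar latitudes (|lat| >= 66.5) are not supported", call. = FALSE)
  }
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  (24 / pi) * acos(clamp(-tan(lat * pi / 180) * tan(delta), -1, 1))
}

#' Daily Thornthwaite potential evapotranspiration
#'
#' The monthly Thornthwaite estimate 16 * (10*T/I)^a, corrected by
#' photoperiod (L/12) and divided by the days in the month to give a daily
#' rate. The exponent is a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I
#' + 0.49239. Zero whenever tmean <= 0.
#'
#' @param tmean Daily mean temperature, degC.
#' @param I Annual heat index (see [annual_heat_index()]).
#' @param L Photoperiod, hours.
#' @param days_in_month Days in the calendar month.
#' @return Potential evapotranspiration, mm/day.
#' @export
daily_thornthwaite_etp <- function(tmean, I, L, days_in_month) {
  if (any(tmean > 0) && I <= 0) {
    stop("heat index I must be positive when tmean > 0", call. = FALSE)
  }
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  etp_month <- ifelse(tmean <= 0, 0, 16 * (10 * pmax(0, tmean) / I)^a)
  etp_month * (L / 12) / days_in_month
}

#' One day of the Dryness Index recursion
#'
#' @param di_prev Yesterday's DI, mm.
#' @param p Daily precipitation, mm.
#' @param etp Daily potential evapotranspiration, mm.
#' @param k1 Crop coefficient for the month, in [0, 1].
#' @param params A [dryness_params()].
#' @return Named numeric: di, tv, es. The reserve is capped above at
#'   `params$cap`; no lower bound is applied, so negative DI is possible and
#'   reported.
#' @export
di_step <- function(di_prev, p, etp, k1, params = dryness_params()) {
  stopifnot(p >= 0, etp >= 0, k1 >= 0, k1 <= 1)
  tv <- k1 * etp
  es <- (1 - k1) * etp * min(p / params$es_rain_scale, 1)
  di <- min(params$cap, di_prev + p - tv - es)
  c(di = di, tv = tv, es = es)
}

# Monthly mean temperatures per calendar year from a daily series; months a
# year lacks are filled with the climatological mean of that month across
# the other years (or, failing that, the series-wide monthly mean), logged
# via message().
monthly_means_by_year <- function(daily) {
  yr <- as.integer(format(daily$date, "%Y"))
  mo <- as.integer(format(daily$date, "%m"))
  all_months <- tapply(daily$tmean, mo, mean)
  clim <- rep(mean(daily$tmean), 12)
  clim[as.integer(names(all_months))] <- as.numeric(all_months)
  out <- list()
  for (y in sort(unique(yr))) {
    m <- tapply(daily$tmean[yr == y], mo[yr == y], mean)
    v <- rep(NA_real_, 12)
    v[as.integer(names(m))] <- as.numeric(m)
    if (anyNA(v)) {
      message(sprintf(
        "heat index for %d: %d missing month(s) filled with climatology",
        y, sum(is.na(v))))
      v[is.na(v)] <- clim[is.na(v)]
    }
    out[[as.character(y)]] <- v
  }
  out
}

#' Run the Dryness Index over a daily series
#'
#' Folds [di_step()] over a contiguous daily series: the reserve starts at
#' `params$w0` on the first day of the window, ETP comes from the daily
#' Thornthwaite formulation (heat index computed per calendar year from the
#' series itself), and k1 follows the monthly schedule. Days with DI
#' strictly below the alert threshold are flagged.
#'
#' For the annual profile start on Jan 1; the seasonal (April--September)
#' variant used by the bioclimatic dryness index is obtained with
#' `start`/`end` set to Apr 1 and Sep 30.
#'
#' @param daily Contiguous daily weather data frame.
#' @param lat Site latitude, decimal degrees.
#' @param params A [dryness_params()].
#' @param start,end Optional window (defaults to the whole series).
#' @return Object of class `dryness_series`: data frame with date, di_mm,
#'   etp_mm, tv_mm, es_mm, alert, plus attributes site_id and params.
#' @export
run_dryness_index <- function(daily, lat, params = dryness_params(),
                              start = NULL, end = NULL) {
  daily <- check_contiguous(daily, "daily series")
  if (!is.null(start) || !is.null(end)) {
    start <- as.Date(start %||% min(daily$date))
    end <- as.Date(end %||% max(daily$date))
    daily <- check_window_coverage(daily, start, end, "dryness window")
  }
  n <- nrow(daily)
  if (n == 0L) stop("empty daily series", call. = FALSE)
  heat <- monthly_means_by_year(daily)
  yr <- format(daily$date, "%Y")
  mo <- as.integer(format(daily$date, "%m"))
  doy <- as.integer(format(daily$date, "%j"))
  di <- etp <- tv <- es <- numeric(n)
  prev <- params$w0
  for (i in seq_len(n)) {
    I <- annual_heat_index(heat[[yr[i]]])
    L <- photoperiod(lat, doy[i])
    etp[i] <- daily_thornthwaite_etp(
      daily$tmean[i], I, L,
      days_in_month(as.integer(yr[i]), mo[i]))
    stepped <- di_step(prev, daily$precip[i], etp[i],
                       params$k1_schedule[mo[i]], params)
    di[i] <- stepped[["di"]]
    tv[i] <- stepped[["tv"]]
    es[i] <- stepped[["es"]]
    prev <- di[i]
  }
  # first day uses w0 as "yesterday's" reserve, matching an initialized store
  out <- data.frame(date = daily$date, di_mm = di, etp_mm = etp, tv_mm = tv,
                    es_mm = es, alert = di < params$alert_threshold,
                    stringsAsFactors = FALSE)
  structure(out, site_id = if (n > 0) daily$site_id[1] else NA_character_,
            params = params, class = c("dryness_series", "data.frame"))
}

#' Irrigation alert events
#'
#' Groups consecutive alert days into events: one event per maximal run,
#' carrying the run's first date and minimum DI.
#'
#' @param series A `dryness_series` from [run_dryness_index()].
#' @return Data frame of events: site_id, kind, date, value (minimum DI in
#'   the run), threshold, run_length.
#' @export
irrigation_alerts <- function(series) {
  params <- attr(series, "params")
  r <- rle(series$alert)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(
    site_id = rep(attr(series, "site_id") %||% NA_character_, length(keep)),
    kind = rep("irrigation", length(keep)),
    date = series$date[starts[keep]],
    value = vapply(keep, function(k)
      min(series$di_mm[starts[k]:ends[k]]), numeric(1)),
    threshold = rep(params$alert_threshold, length(keep)),
    run_length = r$lengths[keep], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @export
print.dryness_series <- function(x, ...) {
  cat(sprintf("Dryness Index series: %d days (%s to %s)\n", nrow(x),
              format(min(x$date)), format(max(x$date))))
  cat(sprintf("  final DI %.1f mm; minimum %.1f mm; %d alert day(s)\n",
              x$di_mm[nrow(x)], min(x$di_mm), sum(x$alert)))
  invisible(x)
}

#' @export
plot.dryness_series <- function(x, ...) {
  graphics::plot(x$date, x$di_mm, type = "l", xlab = "date",
                 ylab = "Dryness Index (mm)", ...)
  graphics::abline(h = attr(x, "params")$alert_threshold, lty = 2)
  invisible(x)
}

#' Load Dryness Index parameters from YAML
#'
#' Recognised keys: w0, cap, alert_threshold, es_rain_scale, k1_schedule
#' (12 monthly values); absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return A [dryness_params()].
#' @export
load_dryness_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  dryness_params(
    w0 = cfg$w0 %||% 200, cap = cfg$cap %||% 200,
    alert_threshold = cfg$alert_threshold %||% 50,
    k1_schedule = if (is.null(cfg$k1_schedule)) default_k1_schedule() else
      as.numeric(cfg$k1_schedule),
    es_rain_scale = cfg$es_rain_scale %||% 5)
}
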