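# Annual viticultural bioclimatic indices and multi-model ensemble climate
# normals. Northern-hemisphere growing season Apr 1 - Oct 31 (Huglin window
# Apr 1 - Sep 30), per the standard index literature.

#' Growing-degree-day sum over a window
#'
#' Sum of max(0, tmean - base) over the window; every day of the window
#' must be present (no silent skipping).
#'
#' @param daily Daily weather data frame.
#' @param base Base temperature, degC.
#' @param start,end Window bounds (dates).
#' @return Degree-day sum, degC day.
#' @export
gdd_sum <- function(daily, base = 10, start, end) {
  win <- check_window_coverage(daily, start, end, "GDD window")
  sum(pmax(0, win$tmean - base))
}

#' Huglin day-length coefficient
#'
#' Standard stepwise table by absolute latitude: 1.00 up to 40 degrees,
#' then 1.02, 1.03, 1.04, 1.05, 1.06 for the 2-degree bands up to 50.
#'
#' @param lat Latitude, decimal degrees.
#' @return Coefficient K.
#' @export
huglin_k <- function(lat) {
  l <- abs(lat)
  if (l <= 40) 1.00
  else if (l <= 42) 1.02
  else if (l <= 44) 1.03
  else if (l <= 46) 1.04
  else if (l <= 48) 1.05
  else if (l <= 50) 1.06
  else stop("Huglin coefficient undefined above 50 degrees latitude",
            call. = FALSE)
}

#' Annual viticultural bioclimatic indices
#'
#' Computes, from one complete civil year of daily weather:
#' annual mean temperature and total precipitation; growing-season (Apr 1 -
#' Oct 31) mean temperature and precipitation; GDD base 10 and the Winkler
#' index (identical by construction); biologically effective degree days
#' (daily contribution capped at 9 degC day); the Huglin heliothermal index
#' over Apr 1 - Sep 30 with the latitude coefficient K; the cool-night
#' index (mean September tmin); the seasonal dryness index (final Sep 30
#' value of the soil-water-balance recursion started Apr 1 at 200 mm); the
#' Branas hydrothermal index (sum over Apr-Aug of monthly mean temperature
#' times monthly precipitation); and the De Martonne aridity index
#' annual_p / (annual_t + 10).
#'
#' @param daily One civil year of daily weather (complete; gap-fill
#'   upstream).
#' @param lat Site latitude, decimal degrees.
#' @param water_params Parameters for the dryness recursion (defaults:
#'   200 mm reserve and cap).
#' @return Object of class `bioclim_indices`: one-row data frame with
#'   site_id, year and the index values, plus an `"extremes"` attribute
#'   (see [extremes_indices()]).
#' @export
compute_annual_indices <- function(daily, lat,
                                   water_params = dryness_params()) {
  daily <- daily[order(daily$date), , drop = FALSE]
  year <- as.integer(format(daily$date[1], "%Y"))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  dec31 <- as.Date(sprintf("%d-12-31", year))
  daily <- check_window_coverage(daily, jan1, dec31,
                                 sprintf("civil year %d", year))
  gs <- daily[daily$date >= as.Date(sprintf("%d-04-01", year)) &
                daily$date <= as.Date(sprintf("%d-10-31", year)), ]
  hug <- daily[daily$date >= as.Date(sprintf("%d-04-01", year)) &
                 daily$date <= as.Date(sprintf("%d-09-30", year)), ]
  sep <- daily[format(daily$date, "%m") == "09", ]

  mo <- as.integer(format(daily$date, "%m"))
  monthly_t <- tapply(daily$tmean, mo, mean)
  monthly_p <- tapply(daily$precip, mo, sum)
  branas <- sum(monthly_t[as.character(4:8)] * monthly_p[as.character(4:8)])

  di <- run_dryness_index(daily, lat, water_params,
                          start = sprintf("%d-04-01", year),
                          end = sprintf("%d-09-30", year))

  annual_t <- mean(daily$tmean)
  annual_p <- sum(daily$precip)
  out <- data.frame(
    site_id = daily$site_id[1], year = year,
    annual_t = annual_t, annual_p = annual_p,
    gst = mean(gs$tmean), gsp = sum(gs$precip),
    gdd10 = sum(pmax(0, gs$tmean - 10)),
    winkler = sum(pmax(0, gs$tmean - 10)),
    bedd = sum(pmin(pmax(0, gs$tmean - 10), 9)),
    huglin = huglin_k(lat) *
      sum(pmax(0, ((hug$tmean - 10) + (hug$tmax - 10)) / 2)),
    cool_night = mean(sep$tmin),
    dryness = di$di_mm[nrow(di)],
    branas = as.numeric(branas),
    de_martonne = annual_p / (annual_t + 10),
    stringsAsFactors = FALSE
  )
  structure(out, extremes = extremes_indices(daily),
            class = c("bioclim_indices", "data.frame"))
}

#' Temperature and precipitation extremes indices
#'
#' An ETCCDI-style minimal set over one civil year: frost days (tmin < 0),
#' summer days (tmax > 25), tropical nights (tmin > 20), hot days
#' (tmax > 35), rx1day (maximum one-day precipitation) and cdd (longest run
#' of days with precipitation < 1 mm). Comparisons are strict.
#'
#' @param daily One civil year of daily weather.
#' @return Named numeric vector.
#' @export
extremes_indices <- function(daily) {
  year <- as.integer(format(daily$date[1], "%Y"))
  daily <- check_window_coverage(daily, sprintf("%d-01-01", year),
                                 sprintf("%d-12-31", year),
                                 sprintf("civil year %d", year))
  dry <- daily$precip < 1
  r <- rle(dry)
  cdd <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  c(frost_days = sum(daily$tmin < 0),
    summer_days = sum(daily$tmax > 25),
    tropical_nights = sum(daily$tmin > 20),
    hot_days = sum(daily$tmax > 35),
    rx1day = max(daily$precip),
    cdd = cdd)
}

#' Ensemble climate normal of an annual index
#'
#' Mean over models of each model's mean over the period years (for equal
#' periods this equals the grand mean over all model-year values).
#'
#' @param per_model_series Named list (by model) of data frames with
#'   columns `year` and `value`.
#' @param scenario Scenario label (e.g. `"ssp126"`, `"ssp370"`, `"ssp585"`,
#'   `"historical"`).
#' @param period Length-2 vector `c(start_year, end_year)`.
#' @param index_name Optional index identifier carried in the result.
#' @return One-row data frame of class `ensemble_normal`: scenario,
#'   period_start, period_end, index, value, n_models.
#' @export
ensemble_normal <- function(per_model_series, scenario, period,
                            index_name = NA_character_) {
  stopifnot(length(period) == 2L, period[1] <= period[2],
            length(per_model_series) >= 1L)
  years <- period[1]:period[2]
  model_means <- vapply(names(per_model_series), function(m) {
    s <- per_model_series[[m]]
    missing <- years[!years %in% s$year]
    if (length(missing) > 0) {
      stop(sprintf("model %s missing year(s) %s in period %d-%d", m,
                   paste(missing, collapse = ", "), period[1], period[2]),
           call. = FALSE)
    }
    mean(s$value[s$year %in% years])
  }, numeric(1))
  structure(
    data.frame(scenario = scenario, period_start = period[1],
               period_end = period[2], index = index_name,
               value = mean(model_means),
               n_models = length(per_model_series),
               stringsAsFactors = FALSE),
    class = c("ensemble_normal", "data.frame"))
}

#' Read a per-model long-format daily climate CSV
#'
#' Columns: model, scenario, date, tmean, tmax, tmin, precip.
#'
#' @param path CSV file.
#' @return Data frame with parsed dates.
#' @export
read_model_daily_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("model", "scenario", "date", "tmean", "precip")
  absent <- setdiff(needed, names(d))
  if (length(absent) > 0) {
    stop("model daily file missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  d$date <- as.Date(d$date)
  d
}
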