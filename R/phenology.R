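# GDD-based phenological stage estimation with dynamic blending of observed
# temperatures and climatological percentile scenarios, plus validation of
# field BBCH records.

#' Phenological calibration for a variety
#'
#' An ordered table of BBCH stages and the cumulative growing-degree-day
#' (base 10 degC, accumulated from Jan 1) threshold at which each stage is
#' expected. A stage flags on the first day the cumulative GDD reaches its
#' threshold (inclusive comparison).
#'
#' @param variety Variety name.
#' @param stages Data frame with columns `bbch` (integer code) and `gdd`
#'   (degC day), thresholds strictly increasing in stage order.
#' @param base_temp Base temperature, degC (default 10).
#' @return Object of class `phenology_calibration`.
#' @export
phenology_calibration <- function(variety, stages, base_temp = 10) {
  stopifnot(is.data.frame(stages), all(c("bbch", "gdd") %in% names(stages)),
            base_temp >= 0)
  if (is.unsorted(stages$gdd, strictly = TRUE)) {
    stop("stage GDD thresholds must be strictly increasing", call. = FALSE)
  }
  structure(list(variety = variety, base_temp = base_temp,
                 stages = stages[, c("bbch", "gdd")]),
            class = "phenology_calibration")
}

#' Shipped calibration for the Vranac variety
#'
#' Field-calibrated thresholds: BBCH 07 (bud burst beginning) at 139, BBCH
#' 65 (full flowering) at 492, BBCH 81 (veraison) at 1203 and BBCH 89
#' (harvest ripeness) at 2188 degC day.
#'
#' @return A [phenology_calibration()].
#' @export
vranac_calibration <- function() {
  load_calibration(system.file("extdata", "vranac.yaml",
                               package = "vitidss", mustWork = TRUE))
}

#' Load a phenological calibration from YAML
#'
#' Expected keys: `variety`, `base_temp`, `stages` (list of `{bbch, gdd}`).
#'
#' @param path YAML file.
#' @return A [phenology_calibration()].
#' @export
load_calibration <- function(path) {
  cfg <- yaml::read_yaml(path)
  phenology_calibration(
    cfg$variety,
    data.frame(bbch = vapply(cfg$stages, function(s) as.integer(s$bbch),
                             integer(1)),
               gdd = vapply(cfg$stages, function(s) as.numeric(s$gdd),
                            numeric(1))),
    base_temp = cfg$base_temp %||% 10)
}

#' Cumulative growing degree days since Jan 1
#'
#' @param daily Daily weather covering Jan 1 through `through`.
#' @param calib A [phenology_calibration()] supplying the base temperature.
#' @param through Last date of the accumulation.
#' @return Cumulative GDD, degC day.
#' @export
cumulative_gdd <- function(daily, calib, through) {
  through <- as.Date(through)
  jan1 <- as.Date(sprintf("%d-01-01", as.integer(format(through, "%Y"))))
  win <- check_window_coverage(daily, jan1, through, "GDD accumulation")
  sum(pmax(0, win$tmean - calib$base_temp))
}

#' Climatological temperature scenarios from multi-year history
#'
#' For every calendar day, the 25th/50th/75th percentiles of daily mean
#' temperature across years give the cold/median/hot scenario series.
#' Percentiles use linear interpolation between order statistics; Feb 29
#' observations are pooled into Feb 28.
#'
#' @param historical_daily Multi-year daily weather data frame (at least 3
#'   distinct years).
#' @return Data frame of class `scenario_series` with columns month, day,
#'   cold, median, hot (365 rows).
#' @export
build_climatology_scenarios <- function(historical_daily) {
  years <- unique(format(historical_daily$date, "%Y"))
  if (length(years) < 3) {
    stop("scenario climatology needs at least 3 years of history",
         call. = FALSE)
  }
  md <- format(historical_daily$date, "%m-%d")
  md[md == "02-29"] <- "02-28"
  q <- t(vapply(split(historical_daily$tmean, md), stats::quantile,
                numeric(3), probs = c(0.25, 0.5, 0.75), names = FALSE))
  keys <- rownames(q)
  out <- data.frame(
    month = as.integer(substr(keys, 1, 2)),
    day = as.integer(substr(keys, 4, 5)),
    cold = q[, 1], median = q[, 2], hot = q[, 3],
    stringsAsFactors = FALSE)
  out <- out[order(out$month, out$day), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("scenario_series", "data.frame"))
}

# Scenario tmean for given dates (Feb 29 borrows Feb 28).
scenario_tmean_for_dates <- function(scenarios, dates, which) {
  mo <- as.integer(format(dates, "%m"))
  dy <- as.integer(format(dates, "%d"))
  dy[mo == 2L & dy == 29L] <- 28L
  key <- match(paste(mo, dy), paste(scenarios$month, scenarios$day))
  scenarios[[which]][key]
}

#' Forecast phenological stage dates
#'
#' Accumulates GDD over the observed series (which must start Jan 1), then
#' continues to Dec 31 with each climatological scenario's daily
#' temperatures. Each stage's predicted date is the first day the
#' cumulative GDD reaches its threshold. Stages already crossed within the
#' observed window are reported once with scenario `"observed"` (their date
#' is identical under every continuation); stages not reached by Dec 31
#' are reported with `reached = FALSE`.
#'
#' @param observed Contiguous daily weather from Jan 1 through the last
#'   reading.
#' @param scenarios A `scenario_series` from [build_climatology_scenarios()].
#' @param calib A [phenology_calibration()].
#' @return Data frame of class `stage_forecast`: variety, bbch, scenario,
#'   predicted_date (NA when not reached), gdd_at_forecast, reached.
#' @export
forecast_stage_dates <- function(observed, scenarios, calib) {
  observed <- check_contiguous(observed, "observed series")
  year <- as.integer(format(observed$date[1], "%Y"))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  if (observed$date[1] != jan1) {
    stop("observed series must start on Jan 1", call. = FALSE)
  }
  dec31 <- as.Date(sprintf("%d-12-31", year))
  last_obs <- max(observed$date)
  future <- if (last_obs < dec31) {
    seq(last_obs + 1, dec31, by = "day")
  } else as.Date(character())

  obs_gdd <- pmax(0, observed$tmean - calib$base_temp)
  n_obs <- length(obs_gdd)
  rows <- list()
  for (sc in c("cold", "median", "hot")) {
    fut_t <- scenario_tmean_for_dates(scenarios, future, sc)
    cum <- cumsum(c(obs_gdd, pmax(0, fut_t - calib$base_temp)))
    dates <- c(observed$date, future)
    for (k in seq_len(nrow(calib$stages))) {
      hit <- which(cum >= calib$stages$gdd[k])[1]
      rows[[length(rows) + 1L]] <- data.frame(
        variety = calib$variety, bbch = calib$stages$bbch[k],
        scenario = if (!is.na(hit) && hit <= n_obs) "observed" else sc,
        predicted_date = if (is.na(hit)) as.Date(NA) else dates[hit],
        gdd_at_forecast = if (is.na(hit)) cum[length(cum)] else cum[hit],
        reached = !is.na(hit), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- unique(out)  # observed-crossed stages collapse across scenarios
  rownames(out) <- NULL
  structure(out, class = c("stage_forecast", "data.frame"))
}

# BBCH codes the platform accepts: the standard observation ranges plus the
# calibrated stage codes.
BBCH_RANGES <- rbind(c(11, 29), c(53, 57), c(60, 69), c(71, 79),
                     c(81, 89), c(91, 99))
BBCH_EXTRA <- c(7L)

bbch_allowed <- function(code) {
  code %in% BBCH_EXTRA |
    apply(outer(code, BBCH_RANGES[, 1], ">=") &
            outer(code, BBCH_RANGES[, 2], "<="), 1, any)
}

#' Validate field phenology records
#'
#' Checks each record's BBCH code against the allowed ranges (leaf
#' development 11-29, inflorescence emergence 53-57, flowering 60-69, fruit
#' development 71-79, ripening 81-89, senescence 91-99, plus calibrated
#' stage 07), rejects future-dated observations, and flags duplicates of
#' (parcel_id, variety, bbch, date) both within the batch and against
#' `existing`. Rejection is a report, never an exception.
#'
#' @param records Data frame with columns parcel_id, date, variety, bbch
#'   (and optionally photo_ref).
#' @param existing Optional data frame of previously accepted records.
#' @param today Reference date for the future-date check.
#' @return The records with added columns `accepted` (logical) and `reason`
#'   (NA when accepted).
#' @export
validate_phenology_record <- function(records, existing = NULL,
                                      today = Sys.Date()) {
  records$date <- as.Date(records$date)
  reason <- rep(NA_character_, nrow(records))
  ok_bbch <- bbch_allowed(as.integer(records$bbch))
  reason[!ok_bbch] <- "BBCH code outside all allowed ranges"
  future <- records$date > as.Date(today)
  reason[is.na(reason) & future] <- "observation date in the future"
  key <- paste(records$parcel_id, records$variety, records$bbch,
               records$date)
  dup <- duplicated(key)
  if (!is.null(existing) && nrow(existing) > 0) {
    old <- paste(existing$parcel_id, existing$variety, existing$bbch,
                 as.Date(existing$date))
    dup <- dup | key %in% old
  }
  reason[is.na(reason) & dup] <- "duplicate record"
  records$accepted <- is.na(reason)
  records$reason <- reason
  records
}

#' Read field phenology records
#'
#' CSV columns: parcel_id, date, variety, bbch, photo_ref (optional).
#'
#' @param path CSV file.
#' @return Data frame with parsed dates.
#' @export
read_phenology_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("parcel_id", "date", "variety", "bbch")
  absent <- setdiff(needed, names(p))
  if (length(absent) > 0) {
    stop("phenology file missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  p$date <- as.Date(p$date)
  p
}

#' @export
print.stage_forecast <- function(x, ...) {
  cat(sprintf("Stage forecasts for %s:\n", x$variety[1]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  BBCH %02d [%s]: %s (GDD %.0f)\n", x$bbch[i],
                x$scenario[i],
                if (x$reached[i]) format(x$predicted_date[i]) else
                  "not reached",
                x$gdd_at_forecast[i]))
  }
  invisible(x)
}
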