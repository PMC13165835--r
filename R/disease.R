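# Goidanich downy-mildew (Plasmopara viticola) risk accumulation.
#
# Two sequential phases: primary infection is triggered by the "3-10 rule"
# (daily rain > 10 mm, mean temperature > 10 degC, shoot length > 10 cm,
# all strict); from activation the cumulative index grows daily,
# GI_t = min(100, GI_{t-1} + f(T_t, RH_t)), with f looked up in an
# increment table by temperature and relative-humidity bin. Recorded spray
# treatments reset GI to zero; in automatic mode a treatment is assumed the
# day after GI first exceeds the alert threshold.

#' Goidanich increment table
#'
#' Daily risk increments (percent/day) indexed by temperature and relative
#' humidity bins. Bins are left-closed, right-open; the topmost bin of each
#' dimension is closed on the right so e.g. RH = 100 is inside. Values
#' outside every bin contribute 0.
#'
#' @param temp_bins Ascending temperature break points, degC (length nT+1).
#' @param rh_bins Ascending relative-humidity break points, % (length nR+1).
#' @param increments nT x nR matrix of non-negative increments, percent/day.
#' @return Object of class `increment_table`.
#' @export
increment_table <- function(temp_bins, rh_bins, increments) {
  increments <- as.matrix(increments)
  if (is.unsorted(temp_bins, strictly = TRUE) ||
      is.unsorted(rh_bins, strictly = TRUE)) {
    stop("increment table bins must be strictly increasing (no overlaps)",
         call. = FALSE)
  }
  if (!all(dim(increments) == c(length(temp_bins) - 1L,
                                length(rh_bins) - 1L))) {
    stop("increment matrix must be (length(temp_bins)-1) x (length(rh_bins)-1)",
         call. = FALSE)
  }
  if (any(increments < 0)) stop("increments must be >= 0", call. = FALSE)
  structure(list(temp_bins = as.numeric(temp_bins),
                 rh_bins = as.numeric(rh_bins), increments = increments),
            class = "increment_table")
}

#' Load an increment table from YAML
#'
#' Expects keys `temp_bins`, `rh_bins`, `increments` (list of rows). The
#' package ships a simplified default table at
#' `system.file("extdata", "goidanich_increments.yaml", package = "vitidss")`,
#' patterned on the shape of the classic Goidanich tables; replace it with a
#' full transcription for operational use.
#'
#' @param path YAML file.
#' @return An [increment_table()].
#' @export
load_increment_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  increment_table(cfg$temp_bins, cfg$rh_bins,
                  do.call(rbind, lapply(cfg$increments, as.numeric)))
}

#' @rdname load_increment_table
#' @export
default_increment_table <- function() {
  load_increment_table(system.file("extdata", "goidanich_increments.yaml",
                                   package = "vitidss", mustWork = TRUE))
}

#' Goidanich model parameters
#'
#' @param rain_activation Daily rain (mm) the 3-10 rule must strictly
#'   exceed (10 mm).
#' @param temp_activation Mean temperature (degC) it must strictly exceed
#'   (10 degC).
#' @param shoot_gdd_threshold Cumulative GDD (base 10, from Jan 1) above
#'   which shoots are taken to exceed 10 cm when the GDD proxy is used.
#' @param alert_threshold Alert level, percent (50); alerts fire strictly
#'   above it.
#' @param cap Upper bound of the index, percent (100).
#' @param table An [increment_table()].
#' @param mode `"manual"` (recorded sprays reset GI), `"automatic"`
#'   (treatment assumed the day after first exceedance), or `"hybrid"`
#'   (both).
#' @param shoot_rule How the shoot-length condition is decided: `"gdd"`
#'   (default, GDD proxy), `"observed"` (true from `shoot_date` on), or
#'   `"always"`.
#' @param shoot_date Observation date for `shoot_rule = "observed"`.
#' @return List of class `goidanich_params`.
#' @export
goidanich_params <- function(rain_activation = 10, temp_activation = 10,
                             shoot_gdd_threshold = 150,
                             alert_threshold = 50, cap = 100,
                             table = default_increment_table(),
                             mode = c("manual", "automatic", "hybrid"),
                             shoot_rule = c("gdd", "observed", "always"),
                             shoot_date = NULL) {
  mode <- match.arg(mode)
  shoot_rule <- match.arg(shoot_rule)
  stopifnot(alert_threshold > 0, alert_threshold < cap,
            inherits(table, "increment_table"))
  if (shoot_rule == "observed" && is.null(shoot_date)) {
    stop("shoot_rule = 'observed' requires shoot_date", call. = FALSE)
  }
  structure(list(rain_activation = rain_activation,
                 temp_activation = temp_activation,
                 shoot_gdd_threshold = shoot_gdd_threshold,
                 alert_threshold = alert_threshold, cap = cap, table = table,
                 mode = mode, shoot_rule = shoot_rule,
                 shoot_date = if (is.null(shoot_date)) NULL else
                   as.Date(shoot_date)),
            class = "goidanich_params")
}

#' 3-10 primary infection rule
#'
#' TRUE iff daily precipitation strictly exceeds the rain threshold, mean
#' temperature strictly exceeds the temperature threshold, and the
#' shoot-length condition holds.
#'
#' @param day One-row daily weather data frame (or list with `precip`,
#'   `tmean`).
#' @param shoot_ok Logical: shoots longer than 10 cm.
#' @param params A [goidanich_params()].
#' @return Logical.
#' @export
check_primary_infection_rule <- function(day, shoot_ok, params) {
  isTRUE(day$precip > params$rain_activation &&
           day$tmean > params$temp_activation && shoot_ok)
}

#' Daily Goidanich increment lookup
#'
#' @param tmean Daily mean temperature, degC.
#' @param rh_mean Daily mean relative humidity, %.
#' @param table An [increment_table()].
#' @return Increment in percent/day; 0 outside all bins or for missing RH.
#' @export
goidanich_increment <- function(tmean, rh_mean, table) {
  goidanich_increments(tmean, rh_mean, table)
}

# vectorised lookup backing goidanich_increment and run_goidanich
goidanich_increments <- function(tmean, rh_mean, table) {
  ti <- findInterval(tmean, table$temp_bins, rightmost.closed = TRUE)
  ri <- findInterval(rh_mean, table$rh_bins, rightmost.closed = TRUE)
  ok <- !is.na(tmean) & !is.na(rh_mean) &
    ti >= 1L & ti <= nrow(table$increments) &
    ri >= 1L & ri <= ncol(table$increments)
  out <- numeric(length(ti))
  out[ok] <- table$increments[cbind(ti[ok], ri[ok])]
  out
}

#' Run the Goidanich risk model over a season
#'
#' Before activation GI is 0. From the first day the 3-10 rule holds
#' (activation is latched for the season), GI accumulates daily increments,
#' capped at `params$cap`. Resets zero GI but do not de-activate:
#' in manual mode recorded spray dates reset; in automatic mode a treatment
#' is assumed, resetting the day after GI first exceeds the alert
#' threshold; hybrid applies both. Alerts flag days with GI strictly above
#' the threshold.
#'
#' @param daily Contiguous daily weather data frame (should start Jan 1
#'   when the GDD shoot proxy is used).
#' @param management Optional management data frame with columns date and
#'   treatment; rows with `treatment == "spray"` are reset dates.
#' @param params A [goidanich_params()].
#' @return Object of class `goidanich_series`: data frame with date, gi,
#'   activated, alert, reset.
#' @export
run_goidanich <- function(daily, management = NULL,
                          params = goidanich_params()) {
  daily <- check_contiguous(daily, "daily series")
  n <- nrow(daily)
  if (n == 0L) stop("empty daily series", call. = FALSE)
  shoot_ok <- switch(
    params$shoot_rule,
    always = rep(TRUE, n),
    observed = daily$date >= params$shoot_date,
    gdd = cumsum(pmax(0, daily$tmean - 10)) >= params$shoot_gdd_threshold)
  if (params$shoot_rule == "gdd" &&
      format(daily$date[1], "%m-%d") != "01-01") {
    warning("GDD shoot proxy accumulates from the series start, ",
            "but the series does not begin on Jan 1", call. = FALSE)
  }
  spray_dates <- if (!is.null(management) &&
                     params$mode %in% c("manual", "hybrid")) {
    as.Date(management$date[management$treatment == "spray"])
  } else as.Date(character())

  auto <- params$mode %in% c("automatic", "hybrid")
  rule_ok <- daily$precip > params$rain_activation &
    daily$tmean > params$temp_activation & shoot_ok
  act_idx <- which(rule_ok)[1]
  inc_all <- goidanich_increments(daily$tmean, daily$rh_mean, params$table)
  is_spray <- daily$date %in% spray_dates
  gi <- numeric(n)
  activated <- logical(n)
  alert <- reset <- logical(n)
  prev <- 0
  reset_tomorrow <- FALSE
  for (i in seq_len(n)) {
    if (reset_tomorrow || is_spray[i]) {
      # the index is zero on the treatment day; accumulation resumes next day
      prev <- 0
      reset[i] <- TRUE
      reset_tomorrow <- FALSE
    } else if (!is.na(act_idx) && i > act_idx) {
      # increments start the day after activation
      gi[i] <- min(params$cap, prev + inc_all[i])
    }
    activated[i] <- !is.na(act_idx) && i >= act_idx
    alert[i] <- gi[i] > params$alert_threshold
    if (auto && alert[i]) reset_tomorrow <- TRUE
    prev <- gi[i]
  }
  structure(data.frame(date = daily$date, gi = gi, activated = activated,
                       alert = alert, reset = reset,
                       stringsAsFactors = FALSE),
            site_id = daily$site_id[1], params = params,
            class = c("goidanich_series", "data.frame"))
}

#' Disease alert events
#'
#' One event at the first day of each maximal run of alert days, carrying
#' the GI value that day and a treatment recommendation.
#'
#' @param series A `goidanich_series` from [run_goidanich()].
#' @param parcel_id Optional parcel identifier for the events.
#' @return Data frame of events: site_id, parcel_id, kind, date, value,
#'   threshold, run_length, message.
#' @export
disease_alerts <- function(series, parcel_id = NA_character_) {
  params <- attr(series, "params")
  r <- rle(series$alert)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(
    site_id = rep(attr(series, "site_id") %||% NA_character_, length(keep)),
    parcel_id = rep(parcel_id, length(keep)),
    kind = rep("disease", length(keep)),
    date = series$date[starts[keep]],
    value = series$gi[starts[keep]],
    threshold = rep(params$alert_threshold, length(keep)),
    run_length = r$lengths[keep],
    message = sprintf(
      "Downy-mildew risk index %.1f%% exceeds %.0f%%: treatment recommended",
      series$gi[starts[keep]], params$alert_threshold),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read vineyard management records
#'
#' CSV columns: parcel_id, date, treatment, variety. Treatments follow the
#' platform vocabulary (spray, winter_pruning, cane_removal, fertilisation,
#' herbicide, trimming, irrigation, other).
#'
#' @param path CSV file.
#' @return Data frame with parsed dates.
#' @export
read_management_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("parcel_id", "date", "treatment")
  absent <- setdiff(needed, names(m))
  if (length(absent) > 0) {
    stop("management file missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  m$date <- as.Date(m$date)
  m
}

#' @export
print.goidanich_series <- function(x, ...) {
  cat(sprintf("Goidanich risk series: %d days (%s to %s)\n", nrow(x),
              format(min(x$date)), format(max(x$date))))
  act <- which(x$activated)
  if (length(act) == 0) {
    cat("  not activated (3-10 rule never satisfied)\n")
  } else {
    cat(sprintf("  activated %s; max GI %.1f%%; %d alert day(s); %d reset(s)\n",
                format(x$date[act[1]]), max(x$gi), sum(x$alert),
                sum(x$reset)))
  }
  invisible(x)
}
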