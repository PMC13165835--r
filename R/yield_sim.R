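# Minimal process-based grapevine growth simulator: intercepted PAR times
# radiation-use efficiency, linear FTSW water limitation, GDD-driven leaf
# area, post-anthesis assimilate partitioning to fruit, and management
# effects (trimming caps LAI, irrigation adds soil water). Final yield is
# the fruit dry biomass at physiological maturity.

#' Vine growth simulator configuration
#'
#' All functional forms are deliberately simple documented defaults chosen
#' for testability; every constant is exposed here. Anthesis and maturity
#' thresholds reuse the Vranac GDD calibration (492 and 2188 degC day).
#'
#' @param rue Radiation-use efficiency, g dry mass per MJ intercepted PAR.
#' @param k_ext Canopy light-extinction coefficient (Beer's law).
#' @param lai_max Maximum leaf area index, m2/m2.
#' @param lai_growth_rate LAI increase per degC day of thermal time.
#' @param ttsw Total transpirable soil water, mm.
#' @param ftsw_crit FTSW below which growth is linearly reduced, in (0, 1).
#' @param fruit_partition Fraction of post-anthesis assimilate allocated to
#'   fruit, in [0, 1].
#' @param anthesis_gdd,maturity_gdd Thermal-time thresholds, degC day
#'   (base 10, from Jan 1).
#' @param trim_lai_cap LAI ceiling enforced while the canopy is trimmed
#'   (NULL = no trimming effect).
#' @param irrigation_mm_per_event Water added by one recorded irrigation
#'   event, mm.
#' @return List of class `vine_sim_config`.
#' @export
vine_sim_config <- function(rue = 1.0, k_ext = 0.5, lai_max = 3,
                            lai_growth_rate = 0.005, ttsw = 150,
                            ftsw_crit = 0.4, fruit_partition = 0.5,
                            anthesis_gdd = 492, maturity_gdd = 2188,
                            trim_lai_cap = NULL,
                            irrigation_mm_per_event = 20) {
  stopifnot(rue > 0, k_ext > 0, lai_max > 0, lai_growth_rate > 0, ttsw > 0,
            ftsw_crit > 0, ftsw_crit < 1, fruit_partition >= 0,
            fruit_partition <= 1, anthesis_gdd > 0,
            maturity_gdd > anthesis_gdd)
  structure(list(rue = rue, k_ext = k_ext, lai_max = lai_max,
                 lai_growth_rate = lai_growth_rate, ttsw = ttsw,
                 ftsw_crit = ftsw_crit, fruit_partition = fruit_partition,
                 anthesis_gdd = anthesis_gdd, maturity_gdd = maturity_gdd,
                 trim_lai_cap = trim_lai_cap,
                 irrigation_mm_per_event = irrigation_mm_per_event),
            class = "vine_sim_config")
}

#' Incident PAR from the daily temperature range
#'
#' Hargreaves-Samani global radiation Rs = 0.16 sqrt(tmax - tmin) Ra, with
#' Ra the FAO-56 extraterrestrial radiation for the latitude and day of
#' year; PAR is taken as half of Rs. Used because the station suite
#' measures no radiation.
#'
#' @param day One-row daily weather (needs tmin, tmax, date) or a full
#'   daily data frame (vectorised).
#' @param lat Latitude, decimal degrees.
#' @return Incident PAR, MJ/m2/day.
#' @export
estimate_radiation <- function(day, lat) {
  doy <- as.integer(format(day$date, "%j"))
  ra <- extraterrestrial_radiation(lat, doy)
  rs <- 0.16 * sqrt(pmax(0, day$tmax - day$tmin)) * ra
  0.5 * rs
}

#' @rdname estimate_radiation
#' @param doy Day of year.
#' @export
extraterrestrial_radiation <- function(lat, doy) {
  gsc <- 0.0820  # solar constant, MJ/m2/min (FAO-56)
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(clamp(-tan(phi) * tan(delta), -1, 1))
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' FTSW growth-limitation multiplier
#'
#' Linear ramp: 1 above the critical fraction, ftsw/ftsw_crit below it.
#'
#' @param ftsw Fraction of transpirable soil water, in [0, 1].
#' @param ftsw_crit Stress-onset fraction, in (0, 1).
#' @return Multiplier in [0, 1].
#' @export
ftsw_stress <- function(ftsw, ftsw_crit) {
  stopifnot(all(ftsw >= 0), all(ftsw <= 1), ftsw_crit > 0, ftsw_crit <= 1)
  pmin(1, ftsw / ftsw_crit)
}

#' One day of vine growth
#'
#' Order of operations: thermal time advances; LAI ramps toward its ceiling
#' (lai_max, or trim_lai_cap while trimmed); biomass grows by
#' rue * PAR * (1 - exp(-k_ext * LAI)) * stress with the stress multiplier
#' taken from the morning FTSW; post-anthesis, a fixed fraction of the gain
#' goes to fruit; the soil store gains rain and irrigation and loses
#' transpiration (canopy-scaled ETP, stress-reduced), clamped to
#' [0, ttsw]; FTSW is updated last.
#'
#' @param state Named list: date, lai, biomass, fruit_biomass, atsw, ftsw,
#'   gdd_cum.
#' @param day One-row daily weather.
#' @param par Incident PAR, MJ/m2.
#' @param etp Daily potential evapotranspiration, mm.
#' @param irrigation_mm Irrigation water applied this day, mm.
#' @param trimmed Whether the trimming LAI cap is active.
#' @param cfg A [vine_sim_config()].
#' @return Updated state list.
#' @export
step_vine_day <- function(state, day, par, etp, irrigation_mm = 0,
                          trimmed = FALSE, cfg = vine_sim_config()) {
  dgdd <- max(0, day$tmean - 10)
  gdd_cum <- state$gdd_cum + dgdd
  cap <- if (trimmed && !is.null(cfg$trim_lai_cap)) {
    min(cfg$lai_max, cfg$trim_lai_cap)
  } else cfg$lai_max
  lai <- min(cap, state$lai + cfg$lai_growth_rate * dgdd)
  stress <- ftsw_stress(state$ftsw, cfg$ftsw_crit)
  intercept <- 1 - exp(-cfg$k_ext * lai)
  db <- cfg$rue * par * intercept * stress
  biomass <- state$biomass + db
  fruit <- state$fruit_biomass +
    if (gdd_cum >= cfg$anthesis_gdd) cfg$fruit_partition * db else 0
  demand <- etp * intercept
  atsw <- clamp(state$atsw + day$precip + irrigation_mm - demand * stress,
                0, cfg$ttsw)
  list(date = day$date, lai = lai, biomass = biomass, fruit_biomass = fruit,
       atsw = atsw, ftsw = atsw / cfg$ttsw, gdd_cum = gdd_cum)
}

#' Run a season of the vine growth simulator
#'
#' Folds [step_vine_day()] over a contiguous daily series starting Jan 1
#' with a full soil water store. Management records couple in: `trimming`
#' activates the LAI cap from its date onward, `irrigation` adds
#' `irrigation_mm_per_event` on its date. Yield is the fruit dry biomass on
#' the day cumulative GDD first reaches `maturity_gdd`; if maturity is not
#' reached the season-end value is reported and flagged immature.
#'
#' @param daily Contiguous daily weather covering the season.
#' @param management Optional management data frame (columns date,
#'   treatment).
#' @param cfg A [vine_sim_config()].
#' @param lat Latitude, decimal degrees.
#' @return Object of class `vine_sim`: list with `trajectory` (data frame:
#'   date, lai, biomass, fruit_biomass, atsw, ftsw, gdd_cum), `final_yield`
#'   (g/m2), `maturity_date` (NA if immature), `mature` (logical).
#' @export
run_yield_simulation <- function(daily, management = NULL,
                                 cfg = vine_sim_config(), lat = 42.44) {
  daily <- check_contiguous(daily, "season series")
  n <- nrow(daily)
  if (n == 0L) stop("empty season series", call. = FALSE)

  trim_from <- irrig_dates <- as.Date(character())
  if (!is.null(management) && nrow(management) > 0) {
    trim_from <- as.Date(management$date[management$treatment == "trimming"])
    irrig_dates <- as.Date(
      management$date[management$treatment == "irrigation"])
  }
  heat <- monthly_means_by_year(daily)
  yr <- format(daily$date, "%Y")
  mo <- as.integer(format(daily$date, "%m"))
  doy <- as.integer(format(daily$date, "%j"))
  par <- estimate_radiation(daily, lat)

  state <- list(date = daily$date[1], lai = 0, biomass = 0,
                fruit_biomass = 0, atsw = cfg$ttsw, ftsw = 1, gdd_cum = 0)
  traj <- vector("list", n)
  maturity_date <- as.Date(NA)
  final_yield <- NA_real_
  for (i in seq_len(n)) {
    I <- annual_heat_index(heat[[yr[i]]])
    L <- photoperiod(lat, doy[i])
    etp <- daily_thornthwaite_etp(daily$tmean[i], I, L,
                                  days_in_month(as.integer(yr[i]), mo[i]))
    irr <- if (daily$date[i] %in% irrig_dates)
      cfg$irrigation_mm_per_event else 0
    trimmed <- length(trim_from) > 0 && any(daily$date[i] >= trim_from)
    state <- step_vine_day(state, daily[i, ], par[i], etp, irr, trimmed, cfg)
    traj[[i]] <- as.data.frame(state, stringsAsFactors = FALSE)
    if (is.na(maturity_date) && state$gdd_cum >= cfg$maturity_gdd) {
      maturity_date <- daily$date[i]
      final_yield <- state$fruit_biomass
    }
  }
  mature <- !is.na(maturity_date)
  if (!mature) final_yield <- state$fruit_biomass
  structure(list(trajectory = do.call(rbind, traj),
                 final_yield = final_yield, maturity_date = maturity_date,
                 mature = mature, config = cfg),
            class = "vine_sim")
}

#' @export
print.vine_sim <- function(x, ...) {
  cat(sprintf("Vine growth simulation: %d days\n", nrow(x$trajectory)))
  if (x$mature) {
    cat(sprintf("  maturity reached %s; yield %.1f g/m2 fruit dry mass\n",
                format(x$maturity_date), x$final_yield))
  } else {
    cat(sprintf("  maturity not reached (immature); fruit biomass %.1f g/m2\n",
                x$final_yield))
  }
  invisible(x)
}

#' @export
plot.vine_sim <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(tr$date, tr$biomass, type = "l", xlab = "date",
                 ylab = "dry biomass (g/m2)", ...)
  graphics::lines(tr$date, tr$fruit_biomass, lty = 2)
  graphics::legend("topleft", legend = c("total", "fruit"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' Load a vine simulator configuration from YAML
#'
#' Any subset of the [vine_sim_config()] arguments may be given; the rest
#' keep their defaults.
#'
#' @param path YAML file.
#' @return A [vine_sim_config()].
#' @export
load_vine_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(vine_sim_config))
  do.call(vine_sim_config, cfg[intersect(names(cfg), known)])
}
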