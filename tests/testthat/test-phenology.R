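test_that("the shipped Vranac calibration loads with its field thresholds", {
  calib <- vranac_calibration()
  expect_equal(calib$variety, "Vranac")
  expect_equal(calib$base_temp, 10)
  expect_equal(calib$stages$bbch, c(7L, 65L, 81L, 89L))
  expect_equal(calib$stages$gdd, c(139, 492, 1203, 2188))
  expect_error(phenology_calibration(
    "x", data.frame(bbch = c(7, 65), gdd = c(500, 400))),
    "strictly increasing")
})

test_that("cumulative GDD matches direct arithmetic", {
  calib <- vranac_calibration()
  d <- constant_year(tmean = 20)
  expect_equal(cumulative_gdd(d, calib, "2025-01-14"), 140)
  cold <- constant_year(tmean = 8)
  expect_equal(cumulative_gdd(cold, calib, "2025-06-30"), 0)
  one <- constant_year(tmean = 12)
  expect_equal(cumulative_gdd(one, calib, "2025-01-01"), 2)
  expect_error(cumulative_gdd(d[-10, ], calib, "2025-02-01"), "missing")
})

test_that("climatology scenarios are daily percentiles across years", {
  base <- do.call(rbind, lapply(2018:2022, function(y)
    constant_year(year = y, tmean = 12)))
  same <- build_climatology_scenarios(base)
  expect_equal(same$cold, same$median)
  expect_equal(same$median, same$hot)
  expect_equal(nrow(same), 365L)

  spread <- base
  jan1 <- format(spread$date, "%m-%d") == "01-01"
  spread$tmean[jan1] <- 1:5
  s <- build_climatology_scenarios(spread)
  d1 <- s[s$month == 1 & s$day == 1, ]
  expect_equal(d1$cold, 2)    # quantile type 7 on {1..5}
  expect_equal(d1$median, 3)
  expect_equal(d1$hot, 4)

  set.seed(5)
  noisy <- generate_daily_weather(weather_gen_params(seed = 5), 2010, 6)
  sn <- build_climatology_scenarios(noisy)
  expect_true(all(sn$cold <= sn$median & sn$median <= sn$hot))

  expect_error(build_climatology_scenarios(constant_year()), "3 years")
})

test_that("stage forecasts cross thresholds inclusively at the printed GDDs", {
  calib <- vranac_calibration()
  d <- constant_year(tmean = 20)
  scen <- build_climatology_scenarios(
    do.call(rbind, lapply(2018:2020, function(y)
      constant_year(year = y, tmean = 20))))
  fc <- forecast_stage_dates(d, scen, calib)
  # constant 20 degC: 10 GDD/day, crossings at days 14/50/121/219
  crossing <- setNames(fc$predicted_date, fc$bbch)
  expect_equal(unname(crossing[c("7", "65", "81", "89")]),
               d$date[c(14, 50, 121, 219)])
  expect_true(all(fc$scenario == "observed"))
  expect_true(all(fc$reached))

  # exact threshold hit flags that day (inclusive >=): 10 GDD/day reaches
  # a 140 threshold on day 14, while 141 needs day 15
  calib_exact <- phenology_calibration(
    "x", data.frame(bbch = c(7, 65), gdd = c(140, 141)))
  fce <- forecast_stage_dates(d, scen, calib_exact)
  expect_equal(fce$predicted_date[fce$bbch == 7], d$date[14])
  expect_equal(fce$predicted_date[fce$bbch == 65], d$date[15])
})

test_that("stages crossed before today are identical across scenarios", {
  calib <- vranac_calibration()
  obs <- constant_year(tmean = 20)[1:60, ]  # 600 GDD observed
  hist <- generate_daily_weather(weather_gen_params(seed = 2), 2015, 5)
  scen <- build_climatology_scenarios(hist)
  fc <- forecast_stage_dates(obs, scen, calib)
  crossed <- fc[fc$bbch %in% c(7, 65), ]
  expect_equal(nrow(crossed), 2L)  # one row each, scenario "observed"
  expect_true(all(crossed$scenario == "observed"))
  expect_equal(crossed$predicted_date, obs$date[c(14, 50)])
})

test_that("warmer continuations never delay a stage (forecast dominance)", {
  calib <- vranac_calibration()
  set.seed(23)
  for (rep in 1:100) {
    hist <- generate_daily_weather(
      weather_gen_params(seed = rep, t_annual_mean = stats::runif(1, 12, 18)),
      2012, 4)
    scen <- build_climatology_scenarios(hist)
    obs <- generate_daily_weather(weather_gen_params(seed = rep + 500),
                                  2025, 1)[1:sample(60:200, 1), ]
    fc <- forecast_stage_dates(obs, scen, calib)
    for (code in unique(fc$bbch)) {
      rows <- fc[fc$bbch == code & fc$reached, ]
      hot <- rows$predicted_date[rows$scenario == "hot"]
      cold <- rows$predicted_date[rows$scenario == "cold"]
      med <- rows$predicted_date[rows$scenario == "median"]
      if (length(hot) == 1 && length(med) == 1) expect_lte(hot, med)
      if (length(med) == 1 && length(cold) == 1) expect_lte(med, cold)
    }
    # dates non-decreasing in stage order within each scenario
    for (sc in unique(fc$scenario)) {
      rows <- fc[fc$scenario == sc & fc$reached, ]
      rows <- rows[order(rows$bbch), ]
      if (nrow(rows) > 1) expect_true(all(diff(rows$predicted_date) >= 0))
    }
  }
})

test_that("extending observations with the median scenario is self-consistent", {
  calib <- vranac_calibration()
  hist <- generate_daily_weather(weather_gen_params(seed = 31), 2015, 5)
  scen <- build_climatology_scenarios(hist)
  obs <- generate_daily_weather(weather_gen_params(seed = 99), 2025, 1)[1:90, ]
  base <- forecast_stage_dates(obs, scen, calib)
  base_med <- base[base$scenario %in% c("observed", "median"), ]
  for (extra in c(10, 40)) {
    ext <- obs[1:(90 + extra), ]
    # continue the observed window with the median scenario's own values
    newdays <- seq(obs$date[90] + 1, by = "day", length.out = extra)
    ext[91:(90 + extra), ] <- obs[rep(1, extra), ]
    ext$date[91:(90 + extra)] <- newdays
    md <- data.frame(month = as.integer(format(newdays, "%m")),
                     day = as.integer(format(newdays, "%d")))
    key <- match(paste(md$month, md$day), paste(scen$month, scen$day))
    ext$tmean[91:(90 + extra)] <- scen$median[key]
    fc2 <- forecast_stage_dates(ext, scen, calib)
    fc2_med <- fc2[fc2$scenario %in% c("observed", "median"), ]
    expect_equal(fc2_med$predicted_date[order(fc2_med$bbch)],
                 base_med$predicted_date[order(base_med$bbch)])
  }
})

test_that("field record validation accepts, rejects and explains", {
  recs <- data.frame(
    parcel_id = c("p1", "p1", "p2", "p1"),
    date = c("2025-05-20", "2025-05-21", "2025-05-20", "2025-05-20"),
    variety = "Vranac", bbch = c(65, 45, 15, 65),
    stringsAsFactors = FALSE)
  v <- validate_phenology_record(recs, today = as.Date("2025-06-01"))
  expect_true(v$accepted[1])
  expect_false(v$accepted[2])
  expect_match(v$reason[2], "BBCH")
  expect_true(v$accepted[3])
  expect_false(v$accepted[4])  # duplicate of row 1
  expect_match(v$reason[4], "duplicate")

  future <- data.frame(parcel_id = "p1", date = "2030-01-01",
                       variety = "Vranac", bbch = 65)
  vf <- validate_phenology_record(future, today = as.Date("2025-06-01"))
  expect_false(vf$accepted)
  expect_match(vf$reason, "future")

  # calibrated stage code 07 is allowed even though it is below range 11-29
  v7 <- validate_phenology_record(
    data.frame(parcel_id = "p1", date = "2025-04-01", variety = "Vranac",
               bbch = 7), today = as.Date("2025-06-01"))
  expect_true(v7$accepted)

  # duplicates against an existing store are rejected too
  vs <- validate_phenology_record(recs[1, ], existing = recs[1, ],
                                  today = as.Date("2025-06-01"))
  expect_false(vs$accepted)
})
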