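test_that("increment tables validate bins and look up left-closed cells", {
  expect_error(increment_table(c(10, 10, 20), c(0, 100), matrix(1, 2, 1)),
               "strictly increasing")
  expect_error(increment_table(c(10, 20), c(0, 100), matrix(-1, 1, 1)),
               ">= 0")
  tbl <- increment_table(c(20, 25), c(75, 100), matrix(5, 1, 1))
  expect_equal(goidanich_increment(22, 80, tbl), 5)
  expect_equal(goidanich_increment(10, 80, tbl), 0)  # below lowest bin
  expect_equal(goidanich_increment(22, 60, tbl), 0)  # below RH bins
  expect_equal(goidanich_increment(20, 80, tbl), 5)  # left edge included
  tbl2 <- increment_table(c(10, 20, 30), c(0, 100), matrix(c(1, 9), 2, 1))
  expect_equal(goidanich_increment(20, 50, tbl2), 9)

  shipped <- default_increment_table()
  expect_s3_class(shipped, "increment_table")
  expect_true(all(shipped$increments >= 0))
})

test_that("the 3-10 rule is strict at all three boundaries", {
  p <- goidanich_params(table = toy_table(), shoot_rule = "always")
  day <- list(precip = 12, tmean = 15)
  expect_true(check_primary_infection_rule(day, TRUE, p))
  expect_false(check_primary_infection_rule(list(precip = 10, tmean = 15),
                                            TRUE, p))
  expect_false(check_primary_infection_rule(list(precip = 12, tmean = 9.9),
                                            TRUE, p))
  expect_false(check_primary_infection_rule(list(precip = 12, tmean = 10),
                                            TRUE, p))
  expect_false(check_primary_infection_rule(day, FALSE, p))
})

# Season with one activating rain day; flat toy increments afterwards.
activated_season <- function(inc = 5, act_day = 100) {
  d <- constant_year(precip = 0)
  d$precip[act_day] <- 12
  list(daily = d,
       params = function(mode) goidanich_params(
         table = toy_table(inc), mode = mode, shoot_rule = "always"))
}

test_that("risk accumulates from the day after activation with strict alerts", {
  s <- activated_season()
  quiet <- constant_year(precip = 0)
  gp <- s$params("manual")
  g0 <- run_goidanich(quiet, params = gp)
  expect_true(all(g0$gi == 0))
  expect_false(any(g0$activated))
  expect_equal(nrow(disease_alerts(g0)), 0L)

  g <- run_goidanich(s$daily, params = gp)
  expect_true(g$activated[100])
  expect_equal(g$gi[100], 0)
  expect_equal(g$gi[100 + 10], 50)
  expect_false(g$alert[100 + 10])     # 50 is not strictly above 50
  expect_equal(g$gi[100 + 11], 55)
  expect_true(g$alert[100 + 11])
  expect_equal(disease_alerts(g)$date[1], s$daily$date[111])

  # a spray six days after activation shifts the crossing by six days
  mgmt <- data.frame(parcel_id = "p", date = s$daily$date[106],
                     treatment = "spray")
  gs <- run_goidanich(s$daily, mgmt, gp)
  expect_true(gs$reset[106])
  first <- which(gs$alert)[1]
  expect_equal(first, 111L + 6L)
})

test_that("the index saturates at 100 and is monotone between resets", {
  s <- activated_season(inc = 10)
  g <- run_goidanich(s$daily, params = s$params("manual"))
  expect_equal(max(g$gi), 100)
  tail_gi <- g$gi[150:200]
  expect_true(all(tail_gi == 100))  # absorbing without resets
  expect_true(all(g$gi >= 0 & g$gi <= 100))
  d <- diff(g$gi)
  expect_true(all(d[!g$reset[-1]] >= 0))
})

test_that("automatic mode equals manual mode with constructed sprays", {
  for (seed in 1:100) {
    w <- generate_daily_weather(weather_gen_params(seed = seed), 2025, 1)
    tbl <- increment_table(c(5, 15, 25, 40), c(40, 70, 100),
                           matrix(c(1, 3, 6, 2, 5, 9), 3, 2))
    auto <- run_goidanich(w, params = goidanich_params(
      table = tbl, mode = "automatic", shoot_rule = "gdd"))
    # construct sprays iteratively from manual runs: after each first
    # exceedance insert a spray the following day and rerun
    sprays <- as.Date(character())
    repeat {
      mgmt <- if (length(sprays) > 0)
        data.frame(parcel_id = "p", date = sprays, treatment = "spray")
      else NULL
      man <- run_goidanich(w, mgmt, goidanich_params(
        table = tbl, mode = "manual", shoot_rule = "gdd"))
      nxt <- which(man$alert & man$date > max(c(sprays, w$date[1] - 1)))[1]
      if (is.na(nxt) || nxt == nrow(man)) break
      sprays <- c(sprays, man$date[nxt] + 1)
    }
    expect_equal(auto$gi, man$gi)
    expect_equal(auto$alert, man$alert)
    # every automatic alert run has length 1 (treatment next day)
    r <- rle(auto$alert)
    if (any(r$values)) expect_true(all(r$lengths[r$values] == 1L))
  }
})

test_that("a sub-threshold season triggers no warning", {
  s <- activated_season(inc = 0.15)
  g <- run_goidanich(s$daily, params = s$params("manual"))
  expect_lt(max(g$gi), 50)
  expect_equal(nrow(disease_alerts(g)), 0L)
})

test_that("the GDD shoot proxy delays activation until ~150 degC day", {
  d <- constant_year(tmean = 15, tmin = 10, tmax = 20, precip = 12,
                     rh = 95)
  g <- run_goidanich(d, params = goidanich_params(table = toy_table(),
                                                  shoot_rule = "gdd"))
  # 5 GDD/day: threshold 150 reached on day 30
  expect_false(any(g$activated[1:29]))
  expect_true(g$activated[30])
})
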