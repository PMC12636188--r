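test_that("solar position matches geometry and an independent ephemeris", {
  # equator, equinox, local solar noon
  eq <- solar_position(0, 0, as.POSIXct("2023-03-20 12:07:00", tz = "UTC"))
  expect_lt(abs(eq - 90), 1)
  # south pole at June solstice: elevation ~ -23.44 all day
  for (h in c(0, 6, 18)) {
    el <- solar_position(-90, 0,
                         as.POSIXct(sprintf("2023-06-21 %02d:00:00", h),
                                    tz = "UTC"))
    expect_lt(abs(el - (-23.44)), 0.5)
  }
  # agreement with the independent NOAA-formula oracle on spread dates
  dates <- as.POSIXct(c("2023-06-21 12:00:00", "2023-01-15 03:30:00",
                        "2022-11-07 21:10:00", "2023-02-28 14:45:00"),
                      tz = "UTC")
  for (d in seq_along(dates)) {
    expect_lt(abs(solar_position(52, 0, dates[d]) -
                    solar_elevation_noaa(52, 0, dates[d])), 0.3)
    # the truncated-Fourier oracle itself drifts a few tenths of a degree
    # at high southern latitudes; allow its documented worst case
    expect_lt(abs(solar_position(-65, 20, dates[d]) -
                    solar_elevation_noaa(-65, 20, dates[d])), 0.5)
  }
})

test_that("twilight detection interpolates crossings and handles polar day", {
  # square wave: dark 18:00-06:00 UTC
  times <- seq(as.POSIXct("2023-02-01 00:00:00", tz = "UTC"),
               as.POSIXct("2023-02-03 00:00:00", tz = "UTC"), by = 300)
  hod <- as.numeric(times - trunc(times, "days"), units = "hours")
  light <- ifelse(hod >= 6 & hod < 18, 60, 0)
  ev <- detect_twilights(data.frame(timestamp = times, light = light), 30)
  expect_equal(nrow(ev), 4)
  tods <- format(ev$timestamp, "%H:%M")
  expect_true(all(tods %in% c("05:57", "06:00", "17:57", "18:00")))
  expect_equal(ev$kind, c("sunrise", "sunset", "sunrise", "sunset"))
  # constant light above threshold: no events
  ev2 <- detect_twilights(data.frame(timestamp = times,
                                     light = rep(60, length(times))), 30)
  expect_equal(nrow(ev2), 0)
  # clean synthetic light: crossing times within one sample of the truth
  lt <- make_light(10, -62, "2023-02-15", "2023-02-18")
  thr <- light_threshold_for(-3.5)
  ev3 <- detect_twilights(lt, thr)
  for (i in seq_len(nrow(ev3))) {
    el <- solar_position(-62, 10, ev3$timestamp[i])
    expect_lt(abs(el - (-3.5)), 0.2)
  }
})

test_that("twilight filter drops spurious nights and big shifts only", {
  lt <- make_light(10, -62, "2023-02-15", "2023-02-19")
  ev <- detect_twilights(lt, light_threshold_for(-3.5))
  expect_identical(filter_twilights(ev), ev)   # clean data unchanged
  # inject a spurious 10-minute night: both bounding events removed
  fake_ss <- data.frame(timestamp = ev$timestamp[1] - 7 * 3600,
                        kind = "sunset")
  fake_sr <- data.frame(timestamp = ev$timestamp[1] - 7 * 3600 + 600,
                        kind = "sunrise")
  dirty <- rbind(fake_ss, fake_sr, ev)
  cleaned <- filter_twilights(dirty)
  expect_false(any(cleaned$timestamp %in%
                     c(fake_ss$timestamp, fake_sr$timestamp)))
  expect_equal(nrow(filter_twilights(ev[0, ])), 0)
})

test_that("position estimation inverts the generator outside the equinox", {
  lt <- make_light(10, -62, "2023-02-10", "2023-03-02")
  ev <- filter_twilights(detect_twilights(lt, light_threshold_for(-3.5)))
  est <- estimate_positions(ev, sun_angle = -3.5)
  ok <- !is.na(est$lat)
  expect_gt(sum(ok), 10)
  expect_lt(median(abs(est$lon[ok] - 10)), 0.5)
  expect_lt(median(abs(est$lat[ok] - (-62))), 1.0)
})

test_that("latitude is flagged undefined in degenerate geometry", {
  # 12 h day with sun angle 0 at the equinox: indeterminate latitude
  ev <- data.frame(
    timestamp = as.POSIXct(c("2023-03-20 06:00:00", "2023-03-20 18:00:00"),
                           tz = "UTC"),
    kind = c("sunrise", "sunset"))
  est <- estimate_positions(ev, sun_angle = 0)
  expect_true(is.na(est$lat[1]))
  expect_false(is.na(est$flag[1]))
  # all undefined latitudes carry a reason
  lt <- make_light(0, -60, "2023-03-10", "2023-03-30")
  est2 <- estimate_positions(
    filter_twilights(detect_twilights(lt, light_threshold_for(-3.5))),
    sun_angle = -3.5)
  expect_true(all(!is.na(est2$flag[is.na(est2$lat)])))
})

test_that("latitude error blows up near the equinox; longitude does not", {
  lt <- make_light(0, -60, "2023-03-01", "2023-04-05")
  ev <- filter_twilights(detect_twilights(lt, light_threshold_for(-3.5)))
  est <- estimate_positions(ev, sun_angle = -3.5)
  d_eq <- abs(as.numeric(as.Date(est$ref_time) - as.Date("2023-03-20")))
  near <- d_eq < 5 & !is.na(est$lat)
  far <- d_eq > 10 & !is.na(est$lat)
  expect_gt(sum(near), 2)
  expect_gt(median(abs(est$lat[near] + 60)),
            median(abs(est$lat[far] + 60)))
  expect_lt(median(abs(est$lon[near] - 0)), 0.5)
})

test_that("screening drops equinox-window, overspeed and on-land estimates", {
  base <- data.frame(
    ref_time = as.POSIXct("2023-02-01 12:00:00", tz = "UTC") +
      c(0, 12, 24, 36) * 3600,
    type = "noon", lon = c(0, 0, 36, 0), lat = c(-60, -60, -60, -60),
    sd_lon_km = 200, sd_lat_km = 200, flag = NA_character_,
    stringsAsFactors = FALSE)
  scr <- screen_estimates(base, speed_limit_kmh = 60)
  expect_false(scr$retained[3])   # ~2000 km in 12 h = 167 km/h
  expect_equal(scr$flag[3], "speed")
  expect_true(all(scr$retained[c(1, 2, 4)]))
  # equinox window
  eq <- base
  eq$ref_time <- as.POSIXct("2023-09-22 12:00:00", tz = "UTC") +
    c(0, 12, 24, 36) * 3600
  scr2 <- screen_estimates(eq, equinox_window_days = 15)
  expect_false(any(scr2$retained))
  expect_true(all(scr2$flag == "equinox"))
  # land mask
  scr3 <- screen_estimates(base[1:2, ],
                           is_land = function(lon, lat) lat < -59)
  expect_false(any(scr3$retained))
  expect_true(all(scr3$flag == "land"))
})

test_that("on-colony calibration recovers the sun angle of the threshold", {
  lt <- make_light(5.2, -63, "2023-02-12", "2023-02-22")
  a <- calibrate_sun_angle(lt, light_threshold_for(-4.2), 5.2, -63)
  expect_lt(abs(a - (-4.2)), 0.2)
})
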