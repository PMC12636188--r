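test_that("immersion reduction integrates state changes exactly", {
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  # wet 12:03-12:07 -> block 12:00 has fraction 0.4
  raw <- data.frame(timestamp = t0 + c(12 * 3600 + 180, 12 * 3600 + 420),
                    state = c("wet", "dry"))
  imm <- reduce_immersion(raw)
  expect_equal(imm$wet_fraction[imm$block_start ==
                                  t0 + 12 * 3600], 0.4)
  # random state-change fixture vs per-second brute-force integration
  set.seed(3)
  n_ch <- 40
  times <- sort(sample(0:86399, n_ch))
  states <- rep(c("wet", "dry"), length.out = n_ch)
  raw2 <- data.frame(timestamp = t0 + times, state = states)
  imm2 <- reduce_immersion(raw2)
  # per-second oracle over the covered span
  span0 <- floor(times[1] / 600) * 600
  span1 <- ceiling(times[n_ch] / 600) * 600
  sec <- span0:(span1 - 1)
  idx <- findInterval(sec, times)
  wet_sec <- idx >= 1 & states[pmax(idx, 1)] == "wet"
  blk <- (sec - span0) %/% 600
  oracle <- tapply(wet_sec, factor(blk, levels = sort(unique(blk))), mean)
  expect_equal(unname(imm2$wet_fraction), unname(as.numeric(oracle)),
               tolerance = 1e-9)
  # conservation: total wet seconds preserved
  expect_equal(sum(imm2$wet_fraction) * 600, sum(wet_sec))
})

test_that("colony-day classification uses a strict dry threshold", {
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  blocks <- t0 + seq(0, 86400 * 3 - 600, by = 600)
  wf <- rep(0, length(blocks))
  day2 <- as.Date(blocks, tz = "UTC") == as.Date("2023-01-02")
  # day 2: exactly 95.0% dry (7.2 wet blocks worth of wet time)
  wf[which(day2)[1:8]] <- c(rep(1, 7), 0.2)
  day3 <- as.Date(blocks, tz = "UTC") == as.Date("2023-01-03")
  wf[day3] <- 0.5
  cd <- classify_colony_days(data.frame(block_start = blocks,
                                        wet_fraction = wf))
  expect_true(cd$colony[cd$day == as.Date("2023-01-01")])   # fully dry
  expect_false(cd$colony[cd$day == as.Date("2023-01-02")])  # exactly 95%
  expect_false(cd$colony[cd$day == as.Date("2023-01-03")])  # 50% wet
  # incomplete day flagged, not classified
  cd2 <- classify_colony_days(data.frame(block_start = blocks[1:100],
                                         wet_fraction = wf[1:100]))
  expect_true(is.na(cd2$colony[cd2$day == as.Date("2023-01-01")]))
  # invariance to appending wholly-dry days outside the window
  extra <- data.frame(block_start = t0 + 86400 * 10 +
                        seq(0, 86399, by = 600),
                      wet_fraction = 0)
  cd3 <- classify_colony_days(rbind(
    data.frame(block_start = blocks, wet_fraction = wf), extra))
  expect_equal(cd3$colony[match(cd$day, cd3$day)], cd$colony)
})

test_that("nest bouts are maximal shaded-colony runs", {
  t0 <- as.POSIXct("2022-11-01 00:00:00", tz = "UTC")
  days <- as.Date("2022-11-01") + 0:14
  # light: shaded (0) on days 1-9 and 11, bright otherwise
  lt_times <- t0 + seq(0, 15 * 86400 - 300, by = 300)
  lday <- as.Date(lt_times, tz = "UTC")
  shaded_days <- c(days[1:9], days[11])
  light <- ifelse(lday %in% shaded_days, 0, 50)
  cd <- data.frame(day = days, dry_fraction = 1,
                   colony = TRUE, complete = TRUE)
  bouts <- detect_nest_bouts(data.frame(timestamp = lt_times,
                                        light = light), cd)
  expect_equal(nrow(bouts), 2)
  expect_equal(bouts$duration_d, c(9, 1))
  # alternating shaded/unshaded: all bouts length 1
  light2 <- ifelse(as.numeric(lday - days[1]) %% 2 == 0, 0, 50)
  bouts2 <- detect_nest_bouts(data.frame(timestamp = lt_times,
                                         light = light2), cd)
  expect_true(all(bouts2$duration_d == 1))
})

test_that("phenology rules: first nest day, exodus, hatch/failure", {
  mk_bouts <- function(starts, ends)
    data.frame(start_day = as.Date(starts), end_day = as.Date(ends),
               duration_d = as.numeric(as.Date(ends) - as.Date(starts)) + 1)
  # calendar-faithful bird: nest 07 Nov-17 Nov, exodus, shifts from 04 Dec
  b <- mk_bouts(c("2022-11-07", "2022-12-04", "2022-12-18", "2023-01-10"),
                c("2022-11-17", "2022-12-10", "2022-12-24", "2023-01-16"))
  ph <- infer_phenology(b, 2022)
  expect_equal(ph$first_nest_day, as.Date("2022-11-07"))
  expect_equal(ph$exodus_start, as.Date("2022-11-18"))
  expect_equal(ph$first_incubation_shift, as.Date("2022-12-04"))
  expect_equal(ph$outcome, "hatched")   # bout starting 10 Jan
  # failure: last bout ends 20 Dec
  b2 <- mk_bouts(c("2022-11-07", "2022-12-04"),
                 c("2022-11-16", "2022-12-20"))
  ph2 <- infer_phenology(b2, 2022)
  expect_equal(ph2$outcome, "failed")
  expect_equal(ph2$failure_date, as.Date("2022-12-20"))
  # no bouts
  ph3 <- infer_phenology(b2[0, ], 2022)
  expect_equal(ph3$outcome, "no_bouts")
})

test_that("end-to-end: generator attendance is recovered from loggers", {
  dom <- shared_domain()
  season <- shared_season()
  trk <- generate_tracks(dom, season, n_birds = 1, seed = 8,
                         stages = c("incubation"))
  tr <- trk[[1]]
  tr <- tr[as.Date(tr$timestamp) <= as.Date("2023-01-20"), ]
  rec <- generate_gls_records(tr, seed = 1)
  cd <- classify_colony_days(rec$immersion)
  # true colony days: full days with state "colony" throughout
  tday <- as.Date(tr$timestamp, tz = "UTC")
  true_colony <- tapply(tr$state == "colony", tday, all)
  common <- intersect(as.character(cd$day[cd$complete]),
                      names(true_colony))
  agree <- mean(cd$colony[match(common, as.character(cd$day))] ==
                  true_colony[common])
  expect_gt(agree, 0.9)
})
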