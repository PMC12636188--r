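# Synthetic bird tracks with known behavioural states. Birds follow the
# breeding calendar: nest bouts at the colony alternate with central-place
# foraging trips. Each trip has a scripted skeleton (overland commute out
# at ~317 deg, at-sea transit to a foraging target set relative to the
# current ice edge, a 3-state foraging phase, return via the inward
# crossing at ~173 deg to the colony) with trip durations drawn from the
# stage's distribution.

#' Breeding calendar with stage windows and trip-duration parameters
#'
#' Stage windows are half-open `[start, end)` UTC calendar-day intervals,
#' ordered and non-overlapping. Defaults follow the phenology of
#' Antarctic-continental snow petrels: first full nest day 7 November,
#' pre-laying exodus from 18 November, first incubation shift 4 December,
#' hatching 14 January; mean (sd) trip durations 7.0 (2.5) d in
#' incubation, 3.8 (0.7) d in brood-guard and 4.6 (1.2) d in post-brood.
#'
#' @param season_start_year Year in which the season begins (October).
#' @return Data frame of class `ir_calendar`: `stage`, `start`, `end`,
#'   `trip_mean_d`, `trip_sd_d`, `colony_mean_d` (mean nest-bout length
#'   between trips).
#' @export
breeding_calendar <- function(season_start_year = 2022) {
  y <- season_start_year
  d <- function(mmdd, yr = y) as.Date(sprintf("%d-%s", yr, mmdd))
  cal <- data.frame(
    stage = c("pre_breeding", "pre_laying", "exodus", "incubation",
              "brood_guard", "post_brood"),
    start = c(d("10-01"), d("11-07"), d("11-18"), d("12-04"),
              d("01-14", y + 1), d("02-05", y + 1)),
    end = c(d("11-07"), d("11-18"), d("12-04"), d("01-14", y + 1),
            d("02-05", y + 1), d("03-16", y + 1)),
    trip_mean_d = c(30, 0, 14, 7.0, 3.8, 4.6),
    trip_sd_d = c(5, 0, 2, 2.5, 0.7, 1.2),
    colony_mean_d = c(0, 9.1, 0, 7.0, 3.8, 0.5),
    stringsAsFactors = FALSE)
  stopifnot(all(cal$start[-1] == cal$end[-nrow(cal)]))
  class(cal) <- c("ir_calendar", "data.frame")
  cal
}

stage_of_date <- function(calendar, date) {
  date <- as.Date(date)
  i <- which(calendar$start <= date & date < calendar$end)
  if (length(i) == 0) NA_character_ else calendar$stage[i[1]]
}

#' Default movement parameters for the 3-state generator
#'
#' Step-length gamma means/sds (km per fix interval) and von Mises
#' turning-angle concentrations for travel, forage and rest, plus the
#' state transition matrix used during the foraging phase. Values are
#' plausible for a small fulmarine petrel at a 30-min fix interval
#' (travel ~30 km/h) and are fully configurable.
#'
#' @param fix_interval_min Fix interval the step scales refer to.
#' @return Parameter list (`step_mean`, `step_sd`, `angle_mean`,
#'   `angle_kappa`, `trans`, `delta`, `zero_mass`).
#' @export
movement_params <- function(fix_interval_min = 30) {
  scl <- fix_interval_min / 30
  list(step_mean = c(travel = 15, forage = 3, rest = 0.3) * scl,
       step_sd = c(travel = 6, forage = 1.5, rest = 0.25) * scl,
       angle_mean = c(0, 0, 0),
       angle_kappa = c(travel = 25, forage = 0.7, rest = 0.2),
       trans = matrix(c(0.85, 0.10, 0.05,
                        0.10, 0.80, 0.10,
                        0.10, 0.20, 0.70), 3, 3, byrow = TRUE),
       delta = c(1, 0, 0),
       zero_mass = c(0, 0, 0))
}

# Draw a truncated-normal trip duration (days).
draw_duration <- function(mean_d, sd_d, min_d = 0.5) {
  repeat {
    d <- stats::rnorm(1, mean_d, sd_d)
    if (d >= min_d) return(d)
  }
}

#' Generate synthetic bird tracks with known states
#'
#' Simulates `n_birds` central-place foragers over the breeding calendar.
#' True behavioural states are one of `"travel"`, `"forage"`, `"rest"`
#' (at sea) and `"colony"`. Outward overland commutes leave the colony at
#' `theta_out` (with von Mises jitter per trip); foraging targets sit
#' `forage_offset_deg` of latitude from the current 15% ice-edge contour;
#' inward commutes aim at the coast point from which `theta_in` leads
#' back to the colony. At-sea positions never fall on land.
#'
#' @param domain An `ir_domain`.
#' @param season An `ir_sic_season` (supplies the edge schedule).
#' @param calendar An `ir_calendar`.
#' @param n_birds Number of birds.
#' @param fix_interval_min True-track sampling interval (minutes).
#' @param params Movement parameters from [movement_params()].
#' @param forage_offset_deg Latitude offset of foraging targets from the
#'   ice edge (default -2: two degrees south).
#' @param heading_jitter_sd Per-trip jitter of commute headings (deg).
#' @param stages Character vector restricting which stages generate
#'   movement (default all).
#' @param seed Integer seed.
#' @return List of track data frames (`bird_id`, `timestamp`, `lon`,
#'   `lat`, `state`, `stage`), one per bird; class `ir_tracks`, with the
#'   drawn trip durations in `attr(, "trip_log")`.
#' @export
generate_tracks <- function(domain, season, calendar = breeding_calendar(),
                            n_birds = 1, fix_interval_min = 30,
                            params = movement_params(fix_interval_min),
                            forage_offset_deg = -2,
                            heading_jitter_sd = 5,
                            stages = calendar$stage, seed = 1L) {
  stopifnot(n_birds >= 1)
  stopifnot(all(abs(rowSums(params$trans) - 1) < 1e-9))
  colony <- as.list(domain$colonies[1, ])
  if (!any(!domain$land)) stop("generate_tracks: no sea in domain")
  set.seed(seed)
  trip_log <- list()
  tracks <- vector("list", n_birds)
  for (b in seq_len(n_birds)) {
    tr <- simulate_bird(domain, season, calendar, colony, b,
                        fix_interval_min, params, forage_offset_deg,
                        heading_jitter_sd, stages)
    tracks[[b]] <- tr$track
    trip_log[[b]] <- tr$trips
  }
  structure(tracks, class = "ir_tracks",
            trip_log = do.call(rbind, trip_log))
}

# One bird's full-season track. Internal; randomness comes from the
# caller's RNG stream.
simulate_bird <- function(domain, season, calendar, colony, bird,
                          dt_min, params, offset_deg, jitter_sd, stages) {
  dt_h <- dt_min / 60
  travel_step <- params$step_mean[1]     # km per interval while commuting
  t0 <- as.POSIXct(paste(calendar$start[1], "00:00:00"), tz = "UTC")
  t_end <- as.POSIXct(paste(calendar$end[nrow(calendar)], "00:00:00"),
                      tz = "UTC")
  rows <- list()
  trips <- list()
  t <- t0
  emit <- function(time, lon, lat, state, stage)
    rows[[length(rows) + 1L]] <<- list(time = as.numeric(time), lon = lon,
                                       lat = lat, state = state,
                                       stage = stage)
  while (t < t_end) {
    stg <- stage_of_date(calendar, as.Date(t))
    crow <- calendar[calendar$stage == stg, ]
    active <- stg %in% stages
    if (!active || crow$trip_mean_d == 0) {
      # nest bout / inactive stage: sit at the colony until the stage or
      # bout ends
      bout_d <- if (crow$colony_mean_d > 0)
        max(draw_duration(crow$colony_mean_d, crow$colony_mean_d * 0.3), 0.5)
      else as.numeric(crow$end - as.Date(t))
      n_steps <- max(1L, round(bout_d * 24 / dt_h))
      stage_end <- as.POSIXct(paste(crow$end, "00:00:00"), tz = "UTC")
      for (k in seq_len(n_steps)) {
        if (t >= t_end || t >= stage_end) break
        emit(t, colony$lon, colony$lat, "colony", stg)
        t <- t + dt_min * 60
      }
      next
    }
    # foraging trip
    dur_d <- draw_duration(crow$trip_mean_d, crow$trip_sd_d)
    trips[[length(trips) + 1L]] <-
      data.frame(bird = bird, stage = stg, start = t, duration_d = dur_d)
    res <- simulate_trip(domain, season, colony, t, dur_d, dt_min, params,
                         offset_deg, jitter_sd, stg, emit)
    t <- res
    # nest bout between trips
    if (crow$colony_mean_d > 0) {
      bout_d <- max(draw_duration(crow$colony_mean_d,
                                  crow$colony_mean_d * 0.2), 0.2)
      n_steps <- max(1L, round(bout_d * 24 / dt_h))
      for (k in seq_len(n_steps)) {
        if (t >= t_end) break
        stg2 <- stage_of_date(calendar, as.Date(t))
        emit(t, colony$lon, colony$lat, "colony", stg2)
        t <- t + dt_min * 60
      }
    }
  }
  df <- do.call(rbind.data.frame, rows)
  track <- data.frame(
    bird_id = sprintf("bird%02d", bird),
    timestamp = as.POSIXct(df$time, tz = "UTC", origin = "1970-01-01"),
    lon = df$lon, lat = df$lat, state = df$state, stage = df$stage,
    stringsAsFactors = FALSE)
  list(track = track,
       trips = if (length(trips)) do.call(rbind, trips) else NULL)
}

# One trip starting at the colony at time t with target duration dur_d
# days; returns the end time. Positions are emitted via emit().
simulate_trip <- function(domain, season, colony, t, dur_d, dt_min,
                          params, offset_deg, jitter_sd, stg, emit) {
  dt_h <- dt_min / 60
  travel_step <- params$step_mean[1]
  t_ret <- t + dur_d * 86400
  # per-trip commute headings with von Mises jitter
  th_out <- (colony$theta_out + stats::rnorm(1, 0, jitter_sd)) %% 360
  th_in <- (colony$theta_in + stats::rnorm(1, 0, jitter_sd)) %% 360
  # foraging target: on the ray's longitude, offset from today's edge
  lon_t <- colony$lon + stats::rnorm(1, 0, 3)
  edge_lat <- season$true_edge_lat(as.Date(t), lon_t)
  target <- c(lon = lon_t, lat = edge_lat + offset_deg)
  pos <- c(colony$lon, colony$lat)
  # inward coast crossing: point from which heading theta_in reaches the
  # colony, i.e. along the reciprocal ray from the colony
  s2 <- tryCatch(
    ray_to_coast(c(colony$lon, colony$lat), (th_in + 180) %% 360,
                 domain$is_land, step_km = 10),
    error = function(e) c(lon = colony$lon,
                          lat = domain$coast_lat_fun(colony$lon) + 0.05))
  state <- 1L  # foraging-phase Markov state
  cur_head <- th_out  # persistent heading for the foraging random walk
  phase <- "out"
  while (t < t_ret + 5 * 86400) {  # hard stop well past the target return
    emit(t, pos[1], pos[2],
         if (phase %in% c("out", "in")) "travel"
         else c("travel", "forage", "rest")[state], stg)
    t <- t + dt_min * 60
    at_sea <- !domain$is_land(pos[1], pos[2])
    # time needed to get home from here, at mean travel speed
    t_home_h <- gc_dist_km(pos[1], pos[2], colony$lon, colony$lat) /
      travel_step * dt_h
    if (phase != "in" &&
        as.numeric(t_ret - t, units = "hours") <= t_home_h * 1.05)
      phase <- "in"
    # one per-step heading wobble for every directed-movement leg (wind
    # drift). Drawing it from the travel state's own von Mises keeps the
    # commute's turning angles in the same emission regime as at-sea
    # travel; a narrower (or zero) commute wobble would create a second,
    # degenerate travel regime that no 3-state model could represent.
    wobble <- function() rvonmises(1, 0, params$angle_kappa[1]) * 180 / pi
    if (phase == "out") {
      brg <- if (!at_sea) (th_out + wobble()) %% 360
             else (gc_bearing(pos[1], pos[2], target[1], target[2]) +
                     wobble()) %% 360
      step <- stats::rgamma(1, shape = (travel_step / params$step_sd[1])^2,
                            rate = travel_step / params$step_sd[1]^2)
      cand <- gc_destination(pos[1], pos[2], brg, step)[1, ]
      if (at_sea && domain$is_land(cand["lon"], cand["lat"]))
        cand <- step_avoid_land(domain, pos, brg, step)
      pos <- c(cand[["lon"]], cand[["lat"]])
      if (at_sea && gc_dist_km(pos[1], pos[2], target[1], target[2]) < 40)
        phase <- "forage"
    } else if (phase == "forage") {
      # birds track the receding edge: retarget to today's edge latitude
      target[2] <- season$true_edge_lat(as.Date(t), target[1]) + offset_deg
      state <- sample.int(3L, 1L, prob = params$trans[state, ])
      step <- stats::rgamma(1, shape = (params$step_mean[state] /
                                          params$step_sd[state])^2,
                            rate = params$step_mean[state] /
                              params$step_sd[state]^2)
      # correlated walk: turn relative to the previous heading, with the
      # leash re-aiming the walk at the target when it strays too far
      leash <- gc_dist_km(pos[1], pos[2], target[1], target[2])
      base <- if (leash > 100)
        gc_bearing(pos[1], pos[2], target[1], target[2])
      else cur_head
      brg <- (base + rvonmises(1, 0, params$angle_kappa[state]) *
                180 / pi) %% 360
      cur_head <- brg
      cand <- gc_destination(pos[1], pos[2], brg, step)[1, ]
      if (domain$is_land(cand["lon"], cand["lat"]))
        cand <- step_avoid_land(domain, pos, brg, step)
      pos <- c(cand[["lon"]], cand[["lat"]])
    } else {  # inward
      d_col <- gc_dist_km(pos[1], pos[2], colony$lon, colony$lat)
      if (d_col <= travel_step) {
        emit(t, colony$lon, colony$lat, "colony", stg)
        return(t + dt_min * 60)
      }
      d_s2 <- gc_dist_km(pos[1], pos[2], s2["lon"], s2["lat"])
      head_to_s2 <- at_sea && d_s2 > 20
      goal <- if (head_to_s2) c(s2[["lon"]], s2[["lat"]])
              else c(colony$lon, colony$lat)
      brg <- (gc_bearing(pos[1], pos[2], goal[1], goal[2]) +
                wobble()) %% 360
      step <- min(stats::rgamma(1,
                                shape = (travel_step /
                                           params$step_sd[1])^2,
                                rate = travel_step /
                                  params$step_sd[1]^2),
                  d_col)
      cand <- gc_destination(pos[1], pos[2], brg, step)[1, ]
      if (head_to_s2 && domain$is_land(cand["lon"], cand["lat"]))
        cand <- step_avoid_land(domain, pos, brg, step)
      pos <- c(cand[["lon"]], cand[["lat"]])
    }
  }
  t
}

# Try rotated bearings until the step stays at sea; as a last resort head
# due north (open ocean in this study system).
step_avoid_land <- function(domain, pos, brg, step) {
  for (rot in c(20, -20, 45, -45, 70, -70, 90, -90, 120, -120)) {
    cand <- gc_destination(pos[1], pos[2], (brg + rot) %% 360, step)[1, ]
    if (!domain$is_land(cand["lon"], cand["lat"])) return(cand)
  }
  gc_destination(pos[1], pos[2], 0, step)[1, ]
}
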