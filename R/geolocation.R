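# Threshold-method light-level geolocation: solar geometry, twilight
# detection from archival max-light series, twilight/position filtering,
# twice-daily position estimation (longitude from the time of local noon or
# midnight, latitude from day length), and screening of unresolvable or
# implausible estimates.

# Low-precision solar ephemeris (Meeus-style): declination (deg), equation
# of time (minutes, apparent - mean solar time) and related angles.
solar_parameters <- function(time) {
  t <- as.POSIXct(time, tz = "UTC")
  n <- as.numeric(julian(t, origin = as.POSIXct("2000-01-01 12:00:00",
                                                tz = "UTC")))
  L <- (280.460 + 0.9856474 * n) %% 360          # mean longitude
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180  # mean anomaly
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 4e-7 * n) * pi / 180          # obliquity
  decl <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda)) * 180 / pi
  eqtime <- 4 * (((L - ra + 180) %% 360) - 180)  # minutes
  list(declination_deg = decl * 180 / pi, eqtime_min = eqtime)
}

#' Solar elevation angle
#'
#' Geometric (unrefracted) solar elevation from a low-precision ephemeris,
#' accurate to within about 0.1 degrees over recent decades.
#'
#' @param lat,lon Observer coordinates (degrees). Vectorised.
#' @param time POSIXct time (UTC).
#' @return Solar elevation in degrees, in `[-90, 90]`.
#' @export
solar_position <- function(lat, lon, time) {
  sp <- solar_parameters(time)
  t <- as.POSIXct(time, tz = "UTC")
  hour <- as.numeric(t - trunc(t, "days"), units = "hours")
  tst_min <- hour * 60 + sp$eqtime_min + 4 * lon  # true solar time, minutes
  ha <- (tst_min / 4 - 180) * pi / 180            # hour angle
  phi <- lat * pi / 180
  decl <- sp$declination_deg * pi / 180
  sin_el <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  asin(pmin(1, pmax(-1, sin_el))) * 180 / pi
}

#' Detect twilight events by the threshold method
#'
#' Scans a max-light series for crossings of a fixed light threshold:
#' an upward crossing is a sunrise, a downward crossing a sunset. Crossing
#' times are linearly interpolated between the two bracketing samples.
#' Days without a crossing (polar day or night) yield no events.
#'
#' @param light Data frame with columns `timestamp` (POSIXct, UTC,
#'   strictly increasing) and `light` (>= 0).
#' @param threshold Light threshold within the observed range.
#' @return Data frame with `timestamp` and `kind` ("sunrise"/"sunset").
#' @export
detect_twilights <- function(light, threshold) {
  if (nrow(light) < 2L)
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      kind = character()))
  stopifnot(!is.unsorted(as.numeric(light$timestamp), strictly = TRUE))
  l <- light$light
  above <- l >= threshold
  i <- which(above[-1] != above[-length(above)])
  if (length(i) == 0L)
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      kind = character()))
  t0 <- as.numeric(light$timestamp[i]); t1 <- as.numeric(light$timestamp[i + 1])
  frac <- (threshold - l[i]) / (l[i + 1] - l[i])
  data.frame(
    timestamp = as.POSIXct(t0 + frac * (t1 - t0), tz = "UTC",
                           origin = "1970-01-01"),
    kind = ifelse(above[i + 1], "sunrise", "sunset"),
    stringsAsFactors = FALSE)
}

#' Filter twilight events
#'
#' Removes implausible twilights: both events bounding a night (sunset to
#' next sunrise) shorter than the minimum night length are dropped, and an
#' event whose time of day shifts by more than the allowed amount from the
#' previous same-kind event is dropped. Deterministic single forward pass.
#'
#' @param events Data frame from [detect_twilights()], time-ordered.
#' @param min_night_h Minimum plausible night duration (hours).
#' @param max_shift_min Maximum day-to-day shift in the time of day of the
#'   same twilight kind (minutes).
#' @return Filtered events data frame.
#' @export
filter_twilights <- function(events, min_night_h = 2, max_shift_min = 120) {
  if (nrow(events) == 0L) return(events)
  drop <- rep(FALSE, nrow(events))
  # Rule 1: spuriously short nights remove both bounding events.
  for (i in seq_len(nrow(events) - 1L)) {
    if (events$kind[i] == "sunset" && events$kind[i + 1] == "sunrise") {
      night_h <- as.numeric(events$timestamp[i + 1] - events$timestamp[i],
                            units = "hours")
      if (night_h < min_night_h) drop[c(i, i + 1L)] <- TRUE
    }
  }
  ev <- events[!drop, , drop = FALSE]
  # Rule 2: large day-to-day shifts relative to the last kept same-kind event.
  keep <- rep(TRUE, nrow(ev))
  last_tod <- c(sunrise = NA_real_, sunset = NA_real_)
  for (i in seq_len(nrow(ev))) {
    tod <- as.numeric(ev$timestamp[i]) %% 86400
    k <- ev$kind[i]
    if (!is.na(last_tod[k])) {
      d <- abs(tod - last_tod[k])
      d <- min(d, 86400 - d) / 60
      if (d > max_shift_min) { keep[i] <- FALSE; next }
    }
    last_tod[k] <- tod
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Solve the day-length equation cos(H) = (sin a - sin phi sin d)/(cos phi
# cos d) for latitude phi (deg), given hour angle H (deg) at twilight, solar
# declination d (deg) and sun angle a (deg). Returns lat or NA + reason.
solve_latitude <- function(H_deg, decl_deg, sun_angle_deg,
                           equinox_decl_deg = 0.5) {
  if (abs(decl_deg) < equinox_decl_deg)
    return(list(lat = NA_real_, reason = "equinox"))
  H <- H_deg * pi / 180; d <- decl_deg * pi / 180
  A <- sin(d); B <- cos(d) * cos(H); C <- sin(sun_angle_deg * pi / 180)
  R <- sqrt(A^2 + B^2)
  if (R < 1e-9) return(list(lat = NA_real_, reason = "degenerate"))
  s <- C / R
  if (abs(s) > 1) return(list(lat = NA_real_, reason = "no_solution"))
  t <- atan2(B, A)
  cand <- c(asin(s) - t, pi - asin(s) - t) * 180 / pi
  cand <- ((cand + 180) %% 360) - 180
  cand <- cand[abs(cand) <= 90]
  if (length(cand) == 0L) return(list(lat = NA_real_, reason = "no_solution"))
  if (length(cand) > 1L) {
    # Day longer than 12 h implies the summer hemisphere (sign of decl).
    want <- if (H_deg > 90) sign(decl_deg) else -sign(decl_deg)
    pick <- cand[sign(cand) == want]
    cand <- if (length(pick) > 0L) pick else cand
  }
  list(lat = cand[1], reason = NA_character_)
}

#' Estimate twice-daily positions from twilight events
#'
#' For each consecutive sunrise-sunset (day) or sunset-sunrise (night)
#' pair: longitude places local apparent noon/midnight at the pair's
#' midpoint (equation of time applied); latitude solves the day-length
#' equation given the inter-twilight interval, the solar declination at the
#' midpoint, and the calibrated sun elevation angle of the light threshold.
#' Degenerate solutions (near-equinox, no real root) yield `NA` latitude
#' with a machine-readable reason flag.
#'
#' @param events Filtered, time-ordered twilight events.
#' @param sun_angle Solar elevation (degrees) corresponding to the light
#'   threshold; default -3.5.
#' @param sd_lon_km,sd_lat_km Nominal 1-sigma position errors attached to
#'   each estimate (km); defaults 200 km.
#' @return Data frame with `ref_time`, `type` ("noon"/"midnight"), `lon`,
#'   `lat`, `sd_lon_km`, `sd_lat_km`, `flag` (NA or reason).
#' @export
estimate_positions <- function(events, sun_angle = -3.5,
                               sd_lon_km = 200, sd_lat_km = 200) {
  n <- nrow(events)
  out <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    k1 <- events$kind[i]; k2 <- events$kind[i + 1]
    if (k1 == k2) next  # unpaired; skipped
    t1 <- events$timestamp[i]; t2 <- events$timestamp[i + 1]
    span_h <- as.numeric(t2 - t1, units = "hours")
    if (span_h <= 0 || span_h >= 24) next
    mid <- t1 + (t2 - t1) / 2
    type <- if (k1 == "sunrise") "noon" else "midnight"
    day_h <- if (type == "noon") span_h else 24 - span_h
    sp <- solar_parameters(mid)
    mid_h <- as.numeric(mid - trunc(mid, "days"), units = "hours")
    # Local apparent noon at longitude L is at UTC 12 - eqtime - L/15.
    lon <- 15 * (12 - mid_h - sp$eqtime_min / 60)
    if (type == "midnight") lon <- lon + 180
    lon <- ((lon + 180) %% 360) - 180
    sol <- solve_latitude(H_deg = day_h * 15 / 2,
                          decl_deg = sp$declination_deg,
                          sun_angle_deg = sun_angle)
    out[[length(out) + 1L]] <- data.frame(
      ref_time = mid, type = type, lon = lon, lat = sol$lat,
      sd_lon_km = sd_lon_km, sd_lat_km = sd_lat_km,
      flag = sol$reason, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(ref_time = as.POSIXct(character(), tz = "UTC"),
                      type = character(), lon = numeric(), lat = numeric(),
                      sd_lon_km = numeric(), sd_lat_km = numeric(),
                      flag = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Screen position estimates
#'
#' Drops (flagging, not silently) estimates within an exclusion window of
#' the equinoxes, estimates implying an implausible sustained travel speed
#' (forward scan against the last retained estimate), and estimates on
#' land. Estimates whose latitude is already undefined are passed through
#' unscreened but excluded from the speed scan.
#'
#' @param estimates Data frame from [estimate_positions()], time-ordered.
#' @param equinox_window_days Half-width of the exclusion window around
#'   20 March and 22 September.
#' @param speed_limit_kmh Maximum sustained speed (km/h).
#' @param min_sustain_h Speed rule applies only across gaps of at least
#'   this many hours.
#' @param is_land Optional predicate `function(lon, lat)`; estimates on
#'   land are dropped.
#' @return The estimates with a logical `retained` column and updated
#'   `flag`s; rows failing a rule have `retained = FALSE`.
#' @export
screen_estimates <- function(estimates, equinox_window_days = 15,
                             speed_limit_kmh = 60, min_sustain_h = 6,
                             is_land = NULL) {
  est <- estimates
  n <- nrow(est)
  est$retained <- TRUE
  if (n == 0L) return(est)
  doy <- as.integer(format(as.Date(est$ref_time), "%j"))
  for (eq_doy in c(79, 265)) {  # ~20 Mar, ~22 Sep
    d <- pmin(abs(doy - eq_doy), 365 - abs(doy - eq_doy))
    hit <- d <= equinox_window_days
    est$retained[hit] <- FALSE
    est$flag[hit] <- ifelse(is.na(est$flag[hit]), "equinox", est$flag[hit])
  }
  if (!is.null(is_land)) {
    has_pos <- !is.na(est$lat)
    on_land <- has_pos & is_land(est$lon, est$lat)
    est$retained[on_land] <- FALSE
    est$flag[on_land] <- ifelse(is.na(est$flag[on_land]), "land",
                                est$flag[on_land])
  }
  # Forward speed scan over retained, fully-defined estimates.
  last <- NA_integer_
  for (i in seq_len(n)) {
    if (!est$retained[i] || is.na(est$lat[i])) next
    if (!is.na(last)) {
      dt_h <- as.numeric(est$ref_time[i] - est$ref_time[last],
                         units = "hours")
      if (dt_h >= min_sustain_h) {
        v <- gc_dist_km(est$lon[last], est$lat[last],
                        est$lon[i], est$lat[i]) / dt_h
        if (v > speed_limit_kmh) {
          est$retained[i] <- FALSE
          est$flag[i] <- ifelse(is.na(est$flag[i]), "speed", est$flag[i])
          next
        }
      }
    }
    last <- i
  }
  est
}

#' Calibrate the sun angle on a known-location period
#'
#' Standard on-colony calibration: for each detected twilight during a
#' period when the bird's position is known, the true solar elevation at
#' the crossing time is computed; the calibrated sun angle is the median
#' of those elevations.
#'
#' @param light Light series (see [detect_twilights()]) from the
#'   known-location period.
#' @param threshold Light threshold used for twilight detection.
#' @param lon,lat Known position (degrees).
#' @return Calibrated sun angle (degrees), or `NA` if no twilights.
#' @export
calibrate_sun_angle <- function(light, threshold, lon, lat) {
  ev <- detect_twilights(light, threshold)
  if (nrow(ev) == 0L) return(NA_real_)
  stats::median(vapply(seq_len(nrow(ev)), function(i)
    solar_position(lat, lon, ev$timestamp[i]), numeric(1)))
}
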