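# Degraded logger records from a true track: archival max-light series at
# 5-min intervals (with nest-cavity shading and optional noise), wet/dry
# immersion reduced to 10-min blocks, and GPS fixes with dropout and
# position noise.

# Interpolated position/state of a track at arbitrary times: positions by
# linear interpolation on the projected plane, state from the most recent
# true fix.
track_at_times <- function(track, times) {
  tt <- as.numeric(track$timestamp)
  qt <- as.numeric(times)
  xy <- polar_xy(track$lon, track$lat)
  x <- stats::approx(tt, xy[, "x"], xout = qt, rule = 2)$y
  y <- stats::approx(tt, xy[, "y"], xout = qt, rule = 2)$y
  idx <- findInterval(qt, tt, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  ll <- polar_lonlat(x, y)
  data.frame(timestamp = times, lon = ll[, "lon"], lat = ll[, "lat"],
             state = track$state[idx])
}

# Light transfer: logistic response of max light (0..light_max) to solar
# elevation, centred on elev0 with softness width_deg.
light_from_elevation <- function(elev, light_max = 64, elev0 = -4.5,
                                 width_deg = 1.5) {
  light_max / (1 + exp(-(elev - elev0) / width_deg))
}

#' Generate geolocator light and immersion records from a true track
#'
#' Light is the logistic-transformed solar elevation at the (interpolated)
#' true position every `light_interval_min` minutes, zeroed while the bird
#' is in the nest cavity (state `"colony"`), optionally degraded by
#' multiplicative noise and random shading events. Immersion is the wet
#' fraction of every 10-min block: wet while in at-sea `forage`/`rest`
#' states, dry in flight and at the colony.
#'
#' @param track One track data frame from [generate_tracks()].
#' @param light_noise_sd Multiplicative lognormal noise sd on light
#'   (0 = clean).
#' @param shading_prob Per-sample probability of a random shading event
#'   (light multiplied by 0-0.2).
#' @param light_interval_min Light sampling interval (default 5).
#' @param light_max Saturation level of the light sensor.
#' @param seed Integer seed.
#' @return List with `light` (`timestamp`, `light`) and `immersion`
#'   (`block_start`, `wet_fraction`).
#' @export
generate_gls_records <- function(track, light_noise_sd = 0,
                                 shading_prob = 0, light_interval_min = 5,
                                 light_max = 64, seed = 1L) {
  t0 <- as.numeric(track$timestamp[1])
  t1 <- as.numeric(track$timestamp[nrow(track)])
  if (t1 - t0 < 86400) stop("generate_gls_records: track spans < 1 day")
  set.seed(seed)
  lt <- as.POSIXct(seq(ceiling(t0 / 300) * 300, t1,
                       by = light_interval_min * 60),
                   tz = "UTC", origin = "1970-01-01")
  at <- track_at_times(track, lt)
  elev <- solar_position(at$lat, at$lon, lt)
  light <- light_from_elevation(elev, light_max = light_max)
  light[at$state == "colony"] <- 0  # shaded inside the nest cavity
  if (light_noise_sd > 0)
    light <- light * exp(stats::rnorm(length(light), 0, light_noise_sd))
  if (shading_prob > 0) {
    sh <- stats::runif(length(light)) < shading_prob
    light[sh] <- light[sh] * stats::runif(sum(sh), 0, 0.2)
  }
  light <- pmin(pmax(light, 0), light_max)
  # immersion: wet during at-sea resting/foraging, dry otherwise
  bt <- seq(floor(t0 / 600) * 600, t1, by = 600)
  wet_sample <- at$state %in% c("forage", "rest")
  blk <- findInterval(as.numeric(lt), bt)
  wet_fraction <- vapply(seq_along(bt), function(i) {
    s <- wet_sample[blk == i]
    if (length(s) == 0) 0 else mean(s)
  }, numeric(1))
  list(light = data.frame(timestamp = lt, light = light),
       immersion = data.frame(
         block_start = as.POSIXct(bt, tz = "UTC", origin = "1970-01-01"),
         wet_fraction = wet_fraction))
}

#' Generate GPS fixes from a true track
#'
#' Samples the true track on a regular interval grid, drops fixes
#' independently with probability `dropout`, and adds isotropic Gaussian
#' position noise on the projected plane (default 0; GPS accuracy of a
#' few tens of metres is negligible at grid scale).
#'
#' @param track One track data frame from [generate_tracks()].
#' @param interval_min Fix interval (minutes), >= 1.
#' @param dropout Per-fix dropout probability.
#' @param noise_sd_km Position noise sd (km).
#' @param seed Integer seed.
#' @return Data frame `bird_id`, `timestamp`, `lon`, `lat`.
#' @export
generate_gps_fixes <- function(track, interval_min = 30, dropout = 0,
                               noise_sd_km = 0, seed = 1L) {
  stopifnot(interval_min >= 1)
  set.seed(seed)
  t0 <- as.numeric(track$timestamp[1])
  t1 <- as.numeric(track$timestamp[nrow(track)])
  ft <- as.POSIXct(seq(t0, t1, by = interval_min * 60),
                   tz = "UTC", origin = "1970-01-01")
  at <- track_at_times(track, ft)
  keep <- stats::runif(length(ft)) >= dropout
  at <- at[keep, , drop = FALSE]
  if (noise_sd_km > 0) {
    xy <- polar_xy(at$lon, at$lat)
    ll <- polar_lonlat(xy[, "x"] + stats::rnorm(nrow(at), 0, noise_sd_km),
                       xy[, "y"] + stats::rnorm(nrow(at), 0, noise_sd_km))
    at$lon <- ll[, "lon"]; at$lat <- ll[, "lat"]
  }
  data.frame(bird_id = track$bird_id[1], timestamp = at$timestamp,
             lon = at$lon, lat = at$lat, stringsAsFactors = FALSE)
}

#' Write and read track tables as CSV
#'
#' Plain-text interchange for track-like tables; timestamps are written
#' as ISO-8601 UTC strings.
#'
#' @param x Data frame with a `timestamp` column.
#' @param path File path.
#' @export
write_track_csv <- function(x, path) {
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("timestamp" %in% names(x))
    x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%OSZ")
  if ("block_start" %in% names(x))
    x$block_start <- as.POSIXct(x$block_start, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%OSZ")
  x
}
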