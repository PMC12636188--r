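# Synthetic seasonal sea ice. Concentration is a deterministic function of
# meridional distance from a receding ice-edge latitude: zero in open water,
# 15% at the edge, ramping south through a marginal ice zone of configured
# width into consolidated pack. The edge recedes poleward from an October
# maximum to a late-summer minimum.

#' Default sea-ice season parameters
#'
#' @param start_date,end_date Season span (Date or "YYYY-MM-DD"); should
#'   cover October-March.
#' @param step_days Days between consecutive rasters.
#' @param edge_lat_start Ice-edge latitude at the start of the season (deg).
#' @param edge_lat_min Minimum (most poleward) edge latitude (deg).
#' @param min_date Date at which the minimum is reached; the edge holds
#'   there for the rest of the season.
#' @param miz_width_km Meridional width of the SIC 30-60% band (km).
#' @param outer_width_km Width of the 0-15% outer fringe north of the edge.
#' @param wiggle_amp_deg,wiggle_wavelength_deg Static zonal modulation of
#'   the edge latitude.
#' @param noise_sd_deg Daily random jitter of the edge latitude (deg);
#'   0 gives a strictly monotone retreat.
#' @param sic_max Concentration of consolidated pack (clip level).
#' @return Parameter list for [generate_sic_season()].
#' @export
sic_season_config <- function(start_date = "2022-10-01",
                              end_date = "2023-03-16",
                              step_days = 1,
                              edge_lat_start = -61.5,
                              edge_lat_min = -69,
                              min_date = "2023-02-15",
                              miz_width_km = 200,
                              outer_width_km = 100,
                              wiggle_amp_deg = 0.3,
                              wiggle_wavelength_deg = 25,
                              noise_sd_deg = 0,
                              sic_max = 0.95) {
  out <- as.list(environment())
  out$start_date <- as.Date(start_date)
  out$end_date <- as.Date(end_date)
  out$min_date <- as.Date(min_date)
  out
}

# Edge latitude (deg) at date d and longitude lon under params p, before
# daily noise. Smooth monotone retreat, clamped at the minimum date.
edge_lat_schedule <- function(p, date, lon = 0) {
  f <- as.numeric(date - p$start_date) /
    max(1, as.numeric(p$min_date - p$start_date))
  f <- pmin(pmax(f, 0), 1)
  f <- f * f * (3 - 2 * f)  # smoothstep: slow start, fast mid-season melt
  p$edge_lat_start + (p$edge_lat_min - p$edge_lat_start) * f +
    p$wiggle_amp_deg * sin(2 * pi * lon / p$wiggle_wavelength_deg)
}

#' Generate a season of synthetic sea-ice concentration rasters
#'
#' @param domain An `ir_domain` from [generate_domain()].
#' @param params Parameters from [sic_season_config()].
#' @param seed Integer seed for the daily edge jitter.
#' @return An object of class `ir_sic_season`: a list of `ir_sic` rasters
#'   (each with `date`, `grid`, `sic` matrix with `NA` over land), plus a
#'   `true_edge_lat(date, lon)` function recording the generating schedule.
#' @export
generate_sic_season <- function(domain, params = sic_season_config(),
                                seed = 1L) {
  p <- params
  if (p$end_date <= p$start_date) stop("generate_sic_season: empty season")
  if (p$miz_width_km <= 0) stop("generate_sic_season: MIZ width must be > 0")
  dates <- seq(p$start_date, p$end_date, by = p$step_days)
  set.seed(seed)
  jitter <- stats::rnorm(length(dates), 0, p$noise_sd_deg)

  grid <- domain$grid
  ll <- grid_centres_lonlat(grid)
  lon <- matrix(ll[, "lon"], grid$nx, grid$ny)
  lat <- matrix(ll[, "lat"], grid$nx, grid$ny)
  slope_in <- 0.30 / p$miz_width_km     # SIC per km south of the edge
  slope_out <- 0.15 / p$outer_width_km  # SIC per km fading north of it

  true_edge <- function(date, lon = 0) {
    i <- match(as.Date(date), dates)
    j <- ifelse(is.na(i), 0, jitter[pmax(i, 1)])
    edge_lat_schedule(p, as.Date(date), lon) + j
  }

  rasters <- lapply(seq_along(dates), function(i) {
    el <- edge_lat_schedule(p, dates[i], lon) + jitter[i]
    d_km <- (el - lat) * 111.195  # positive south of the edge
    sic <- ifelse(d_km >= 0,
                  pmin(p$sic_max, 0.15 + d_km * slope_in),
                  pmax(0, 0.15 + d_km * slope_out))
    sic[domain$land] <- NA_real_
    structure(list(date = dates[i], grid = grid, sic = sic),
              class = "ir_sic")
  })
  structure(list(rasters = rasters, dates = dates, params = p,
                 true_edge_lat = true_edge, seed = seed),
            class = "ir_sic_season")
}

#' @export
print.ir_sic_season <- function(x, ...) {
  cat(sprintf("<ir_sic_season: %d rasters, %s to %s>\n",
              length(x$rasters), format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

# Raster for a given date (nearest available).
sic_at_date <- function(season, date) {
  i <- which.min(abs(as.numeric(season$dates - as.Date(date))))
  season$rasters[[i]]
}
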