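# End-to-end synthetic-season pipeline: generate a study system, track a
# cohort with GPS, split and classify trips, compute biological distances
# and foraging-range summaries, and relate foraging latitude to the ice
# edge. This is the package's worked analysis in one call; the acceptance
# script and the end-to-end tests both run it.

#' Run the full pipeline on a synthetic breeding season
#'
#' Generates a domain, a receding ice season and `n_birds` GPS-tracked
#' birds over the given breeding stages; splits tracks into foraging
#' trips, regularises them, fits the 3-state movement HMM and decodes
#' foraging locations; computes per-trip biological distances (d50, d95,
#' dmax) over the sea-passable cost surface; and summarises median
#' foraging latitude against median ice-edge latitude per stage.
#'
#' @param seed Integer seed driving every stochastic component.
#' @param n_birds Cohort size (default 20).
#' @param stages Breeding stages to simulate (default exodus through
#'   brood-guard, the GPS-trackable heart of the season).
#' @param forage_offset_deg True latitude offset of foraging from the ice
#'   edge (default -2).
#' @param edge_lat_min Seasonal minimum edge latitude; the default keeps
#'   the late-season ice edge just north of the coast.
#' @param cost_cell_km Cost-surface cell size (km). The default 25 km
#'   trades the fine operational grid for tractable run time; distances
#'   change by well under the grid's discretisation bound.
#' @param hmm_starts Random restarts for the HMM fit.
#' @param hmm_fit_max_steps Cap on pooled steps used for fitting (the
#'   decode always uses all fixes).
#' @return List with `domain`, `season`, `trips` (per-trip table: bird,
#'   stage, departure, duration_d, d50/d95/dmax, crossings), `stage_summary`
#'   (per stage: median d50, median foraging latitude, median edge
#'   latitude), `offset_fit` (latitude regression), `hmm` (the fit),
#'   `decode_truth_agreement` (decoded vs generator state agreement).
#' @export
run_synthetic_pipeline <- function(seed = 1L, n_birds = 20,
                                   stages = c("exodus", "incubation",
                                              "brood_guard"),
                                   forage_offset_deg = -2,
                                   edge_lat_min = -68,
                                   cost_cell_km = 25,
                                   hmm_starts = 8,
                                   hmm_fit_max_steps = 15000) {
  seed <- as.integer(seed)
  domain <- generate_domain(seed = seed)
  season <- generate_sic_season(
    domain, sic_season_config(edge_lat_min = edge_lat_min), seed = seed)
  calendar <- breeding_calendar()
  tracks <- generate_tracks(domain, season, calendar, n_birds = n_birds,
                            forage_offset_deg = forage_offset_deg,
                            stages = stages, seed = seed)
  colony <- as.list(domain$colonies[1, ])

  # GPS sampling, trip splitting, regularisation
  all_trips <- list()
  for (b in seq_along(tracks)) {
    fixes <- generate_gps_fixes(tracks[[b]], interval_min = 30,
                                seed = seed + b)
    for (tr in split_trips(fixes, colony, radius_km = 5,
                           min_duration_h = 12)) {
      reg <- regularize(tr, interval_min = 30)
      reg$bird_id <- tr$bird_id[1]
      attr(reg, "departure") <- attr(tr, "departure")
      attr(reg, "return_time") <- attr(tr, "return_time")
      all_trips[[length(all_trips) + 1L]] <- reg
    }
  }

  # movement HMM over pooled steps/angles; decode per trip
  sa_list <- lapply(all_trips, function(tr) steps_and_angles(tr$lon,
                                                             tr$lat))
  steps <- unlist(lapply(sa_list, `[[`, "steps"))
  angles <- unlist(lapply(sa_list, `[[`, "angles"))
  sub <- seq_len(min(length(steps), hmm_fit_max_steps))
  hmm <- suppressWarnings(fit_hmm(steps[sub], angles[sub],
                                  n_starts = hmm_starts, seed = seed))

  surface <- cache_surface_graph(
    build_cost_surface(domain, cell_km = cost_cell_km))
  field_cache <- new.env(parent = emptyenv())
  get_field <- function(lonlat) {
    cell <- snap_to_passable(surface, lonlat[1], lonlat[2], max_cells = 6)
    key <- paste(cell["ix"], cell["iy"])
    if (is.null(field_cache[[key]]))
      field_cache[[key]] <- distance_field(surface,
                                           c(cell["ix"], cell["iy"]),
                                           origin_is_cell = TRUE)
    field_cache[[key]]
  }

  trip_rows <- list()
  forage_rows <- list()
  truth_hits <- 0; truth_n <- 0
  for (k in seq_along(all_trips)) {
    tr <- all_trips[[k]]
    sa <- sa_list[[k]]
    states <- decode_states(sa$steps, sa$angles, hmm)
    fix_state <- c(states[1], states)   # state of the step into each fix
    forage <- extract_foraging(tr, states)[, c("timestamp", "lon", "lat")]
    # decoded vs generator truth where the true track has the same stamp
    b <- match(tr$bird_id[1], vapply(tracks, function(x) x$bird_id[1],
                                     character(1)))
    tru <- tracks[[b]]
    m <- match(as.numeric(tr$timestamp), as.numeric(tru$timestamp))
    ok <- !is.na(m) & tru$state[m] %in% c("travel", "forage", "rest")
    truth_map <- c(travel = 1L, forage = 2L, rest = 3L)
    truth_hits <- truth_hits + sum(truth_map[tru$state[m[ok]]] ==
                                     fix_state[ok])
    truth_n <- truth_n + sum(ok)
    cc <- coast_crossings(tr, domain, colony)
    if (is.na(cc$flag) && nrow(forage) > 0) {
      f1 <- get_field(cc$s1); f2 <- get_field(cc$s2)
      d_c_s1 <- gc_dist_km(colony$lon, colony$lat, cc$s1["lon"],
                           cc$s1["lat"])
      d_s2_c <- gc_dist_km(cc$s2["lon"], cc$s2["lat"], colony$lon,
                           colony$lat)
      d <- (d_c_s1 + field_at(f1, forage$lon, forage$lat) +
              field_at(f2, forage$lon, forage$lat) + d_s2_c) / 2
      d <- d[is.finite(d)]
    } else d <- numeric(0)
    dep <- attr(tr, "departure")
    stage <- stage_of_date(calendar, as.Date(dep))
    if (nrow(forage) > 0)
      forage_rows[[length(forage_rows) + 1L]] <-
        data.frame(bird_id = tr$bird_id[1], stage = stage,
                   lon = forage$lon, lat = forage$lat,
                   stringsAsFactors = FALSE)
    trip_rows[[k]] <- data.frame(
      bird_id = tr$bird_id[1], stage = stage, departure = dep,
      duration_d = as.numeric(attr(tr, "return_time") - dep,
                              units = "days"),
      n_forage = nrow(forage),
      d50 = if (length(d)) stats::median(d) else NA_real_,
      d95 = if (length(d)) unname(stats::quantile(d, 0.95)) else NA_real_,
      dmax = if (length(d)) max(d) else NA_real_,
      s1_lon = if (!is.null(cc$s1)) unname(cc$s1["lon"]) else NA_real_,
      s2_lon = if (!is.null(cc$s2)) unname(cc$s2["lon"]) else NA_real_,
      theta_out = cc$theta_out, theta_in = cc$theta_in,
      forage_lat_med = if (nrow(forage)) stats::median(forage$lat)
                       else NA_real_,
      stringsAsFactors = FALSE)
  }
  trips <- do.call(rbind, trip_rows)

  # stage summaries: cohort medians and the matching ice-edge latitude
  trip_log <- attr(tracks, "trip_log")
  stage_summary <- do.call(rbind, lapply(unique(trips$stage), function(s) {
    sel <- trips$stage == s & !is.na(trips$d50)
    win <- calendar[calendar$stage == s, ]
    dates <- season$dates[season$dates >= win$start &
                            season$dates < win$end]
    dates <- dates[seq(1, length(dates), by = 7)]
    edge_lat <- stats::median(vapply(dates, function(d)
      median_edge_latitude(extract_ice_edge(sic_at_date(season, d),
                                            outer_only = TRUE),
                           -20, 30), numeric(1)), na.rm = TRUE)
    data.frame(stage = s,
               n_trips = sum(sel),
               d50_med = stats::median(trips$d50[sel]),
               duration_mean_d = mean(trips$duration_d[trips$stage == s]),
               duration_drawn_mean_d =
                 mean(trip_log$duration_d[trip_log$stage == s]),
               forage_lat_med = stats::median(trips$forage_lat_med[sel],
                                              na.rm = TRUE),
               edge_lat_med = edge_lat,
               stringsAsFactors = FALSE)
  }))

  offset_fit <- if (nrow(stage_summary) >= 3)
    latitude_regression(stage_summary$forage_lat_med,
                        stage_summary$edge_lat_med)
  else NULL

  list(domain = domain, season = season, calendar = calendar,
       trips = trips, trip_log = trip_log, stage_summary = stage_summary,
       forage_points = if (length(forage_rows))
         do.call(rbind, forage_rows) else NULL,
       offset_fit = offset_fit, hmm = hmm,
       decode_truth_agreement = truth_hits / max(truth_n, 1))
}
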