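# Sea-ice metrics: ice-edge extraction (15% concentration contour cells),
# sector median edge latitude, marginal-ice-zone frequency, colony-to-edge
# biological-distance climatology, and the foraging-latitude vs
# edge-latitude regression.

#' Construct a sea-ice concentration raster
#'
#' @param grid An `ir_grid`.
#' @param sic nx x ny matrix of concentrations in `[0, 1]`; `NA` = missing
#'   (e.g. land).
#' @param date Date of the raster.
#' @return Object of class `ir_sic`.
#' @export
sic_grid <- function(grid, sic, date) {
  stopifnot(nrow(sic) == grid$nx, ncol(sic) == grid$ny)
  if (any(sic < 0 | sic > 1, na.rm = TRUE))
    stop("sic_grid: concentrations outside [0, 1]")
  structure(list(date = as.Date(date), grid = grid, sic = sic),
            class = "ir_sic")
}

#' Extract the ice edge from a concentration raster
#'
#' Edge cells are cells at or above the threshold with at least one
#' 4-neighbour below it. With `outer_only = TRUE` only the most equatorward
#' (here: northernmost) crossing per 1-degree longitude bin is kept, which
#' excludes interior polynya edges from edge-latitude summaries.
#'
#' @param sic An `ir_sic`.
#' @param threshold Concentration threshold (default 0.15, the
#'   operational ice-edge definition).
#' @param outer_only Keep only the outermost crossing per longitude bin.
#' @param lon_bin_deg Bin width for `outer_only` (degrees).
#' @return Object of class `ir_ice_edge`: `date`, `grid`, `cells`
#'   (two-column ix/iy matrix), `lonlat` (cell centres), `threshold`.
#' @export
extract_ice_edge <- function(sic, threshold = 0.15, outer_only = FALSE,
                             lon_bin_deg = 1) {
  s <- sic$sic
  if (all(is.na(s))) stop("extract_ice_edge: all-missing raster")
  nx <- nrow(s); ny <- ncol(s)
  above <- !is.na(s) & s >= threshold
  below <- !is.na(s) & s < threshold
  nb_below <- matrix(FALSE, nx, ny)
  nb_below[-nx, ] <- nb_below[-nx, ] | below[-1, ]
  nb_below[-1, ] <- nb_below[-1, ] | below[-nx, ]
  nb_below[, -ny] <- nb_below[, -ny] | below[, -1]
  nb_below[, -1] <- nb_below[, -1] | below[, -ny]
  edge <- above & nb_below
  idx <- which(edge, arr.ind = TRUE)
  colnames(idx) <- c("ix", "iy")
  ll <- grid_centres_lonlat(sic$grid)
  lin <- (idx[, "iy"] - 1L) * nx + idx[, "ix"]
  lonlat <- ll[lin, , drop = FALSE]
  if (outer_only && nrow(idx) > 0) {
    bin <- floor(lonlat[, "lon"] / lon_bin_deg)
    keep <- unlist(lapply(split(seq_len(nrow(idx)), bin), function(i)
      i[which.max(lonlat[i, "lat"])]))
    idx <- idx[keep, , drop = FALSE]
    lonlat <- lonlat[keep, , drop = FALSE]
  }
  structure(list(date = sic$date, grid = sic$grid, cells = idx,
                 lonlat = lonlat, threshold = threshold,
                 outer_only = outer_only),
            class = "ir_ice_edge")
}

#' Median ice-edge latitude within a longitude sector
#'
#' @param edge An `ir_ice_edge`.
#' @param lon_min,lon_max Sector bounds (degrees); default 35W-25E.
#' @return Median latitude (degrees) of edge-cell centres in the sector,
#'   or `NA` (with a warning) when the sector holds no edge cells.
#' @export
median_edge_latitude <- function(edge, lon_min = -35, lon_max = 25) {
  sel <- edge$lonlat[, "lon"] >= lon_min & edge$lonlat[, "lon"] <= lon_max
  if (!any(sel)) {
    warning("median_edge_latitude: no edge cells in sector")
    return(NA_real_)
  }
  stats::median(edge$lonlat[sel, "lat"])
}

#' Marginal-ice-zone frequency raster
#'
#' Per-cell fraction of dates on which concentration lies within the
#' closed band (default 30-60%, the MIZ proxy).
#'
#' @param sic_list List of `ir_sic` on one grid (e.g.
#'   `season$rasters`).
#' @param band Length-2 concentration band.
#' @return Object of class `ir_sic` whose `sic` matrix holds frequencies
#'   and whose date is the first raster's.
#' @export
miz_frequency <- function(sic_list, band = c(0.30, 0.60)) {
  stopifnot(length(sic_list) >= 1)
  g <- sic_list[[1]]$grid
  acc <- matrix(0, g$nx, g$ny)
  nobs <- matrix(0, g$nx, g$ny)
  for (s in sic_list) {
    if (!grid_same(s$grid, g)) stop("miz_frequency: grid mismatch")
    ok <- !is.na(s$sic)
    acc[ok] <- acc[ok] + (s$sic[ok] >= band[1] & s$sic[ok] <= band[2])
    nobs[ok] <- nobs[ok] + 1
  }
  freq <- ifelse(nobs > 0, acc / nobs, NA_real_)
  structure(list(date = sic_list[[1]]$date, grid = g, sic = freq),
            class = "ir_sic")
}

#' Colony-to-ice-edge distance climatology
#'
#' For each raster date: the mean biological distance from the colony to
#' all cells intersecting the ice-edge contour that lie within `cap_km`
#' of the colony (days with no edge cell within the cap are flagged
#' missing). Daily values are then averaged within breeding-stage windows
#' per season, and across seasons into a stage climatology.
#'
#' @param field An `ir_distance_field` of biological distances from the
#'   colony (see [biological_distance_field()] via [project_ranges()]).
#' @param edges List of `ir_ice_edge` (one per date).
#' @param cap_km Maximum distance of included edge cells (default
#'   2330 km, the maximum observed foraging range).
#' @param stage_windows Data frame with `stage`, `start`, `end` (Dates,
#'   half-open `[start, end)`) defining breeding-stage windows; a `season`
#'   column may mark multiple years.
#' @return List with `daily` (date, mean_km, n_cells), `by_stage`
#'   (stage, season, mean_km), `climatology` (stage, mean_km, sd_km).
#' @export
colony_edge_distance <- function(field, edges, cap_km = 2330,
                                 stage_windows = NULL) {
  daily <- do.call(rbind, lapply(edges, function(e) {
    if (nrow(e$cells) == 0)
      return(data.frame(date = e$date, mean_km = NA_real_, n_cells = 0L))
    d <- field$dist_km[e$cells]
    d <- d[is.finite(d) & d <= cap_km]
    data.frame(date = e$date,
               mean_km = if (length(d)) mean(d) else NA_real_,
               n_cells = length(d))
  }))
  out <- list(daily = daily)
  if (!is.null(stage_windows)) {
    sw <- stage_windows
    if (is.null(sw$season)) sw$season <- format(sw$start, "%Y")
    by_stage <- do.call(rbind, lapply(seq_len(nrow(sw)), function(i) {
      sel <- daily$date >= sw$start[i] & daily$date < sw$end[i] &
        !is.na(daily$mean_km)
      data.frame(stage = sw$stage[i], season = sw$season[i],
                 mean_km = if (any(sel)) mean(daily$mean_km[sel])
                           else NA_real_)
    }))
    clim <- stats::aggregate(mean_km ~ stage, data = by_stage,
                             FUN = function(v) c(mean = mean(v), sd = stats::sd(v)),
                             na.action = stats::na.omit)
    clim <- data.frame(stage = clim$stage, mean_km = clim$mean_km[, "mean"],
                       sd_km = clim$mean_km[, "sd"])
    out$by_stage <- by_stage
    out$climatology <- clim
  }
  out
}

#' Regression of foraging latitude on ice-edge latitude
#'
#' Ordinary least squares of median foraging latitude on median ice-edge
#' latitude across stage/colony/season groups, plus the mean meridional
#' offset (foraging minus edge; negative = south of the edge).
#'
#' @param foraging_lat,edge_lat Paired observations (degrees), >= 3.
#' @return List with `slope`, `intercept`, `residual_sd`, `offset_deg`,
#'   `n`, and the fitted `lm` object.
#' @export
latitude_regression <- function(foraging_lat, edge_lat) {
  ok <- is.finite(foraging_lat) & is.finite(edge_lat)
  if (sum(ok) < 3) stop("latitude_regression: need >= 3 paired points")
  fit <- stats::lm(foraging_lat[ok] ~ edge_lat[ok])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residual_sd = stats::sigma(fit),
       offset_deg = mean(foraging_lat[ok] - edge_lat[ok]),
       n = sum(ok), fit = fit)
}
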