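# Utilisation distributions: error-propagated fixed-bandwidth KDE for
# geolocator estimates, autocorrelation-adjusted KDE for GPS foraging
# locations, per-cell population averaging, and 50/95% cumulative-UD
# regions. UDs are per-cell probability masses on an `ir_grid` that sum
# to 1; provenance (method, bandwidth, birds) travels with the object.

#' Build a UD grid covering a set of points
#'
#' @param points Two-column matrix or data frame of `lon`, `lat`.
#' @param cell_km Cell size (km).
#' @param margin_km Margin beyond the point extent on every side;
#'   conventionally at least 3 bandwidths.
#' @return An `ir_grid` snapped to multiples of the cell size.
#' @export
ud_grid_for_points <- function(points, cell_km, margin_km) {
  xy <- polar_xy(points[[1]], points[[2]])
  x0 <- floor((min(xy[, "x"]) - margin_km) / cell_km) * cell_km
  y0 <- floor((min(xy[, "y"]) - margin_km) / cell_km) * cell_km
  nx <- ceiling((max(xy[, "x"]) + margin_km - x0) / cell_km)
  ny <- ceiling((max(xy[, "y"]) + margin_km - y0) / cell_km)
  make_grid(x0, y0, nx, ny, cell_km)
}

#' Propagate geolocation error by location augmentation
#'
#' Draws `n` perturbed replicates of every estimate, with independent
#' Gaussian errors in latitude and longitude whose standard deviations
#' are given in km and converted to degrees at each estimate's latitude.
#' Draws falling on land are retained (they carry estimation error, not
#' habitat information) but flagged when a land predicate is supplied.
#'
#' @param estimates Data frame with `lon`, `lat` (rows with `NA` latitude
#'   are skipped).
#' @param sd_lat_km,sd_lon_km Error standard deviations (km); default
#'   200 km each.
#' @param n Replicates per estimate (default 100).
#' @param seed Integer seed.
#' @param is_land Optional predicate for flagging draws on land.
#' @return Data frame `lon`, `lat`, `source_row`, `on_land`.
#' @export
augment_gls_locations <- function(estimates, sd_lat_km = 200,
                                  sd_lon_km = 200, n = 100, seed = 1L,
                                  is_land = NULL) {
  stopifnot(sd_lat_km >= 0, sd_lon_km >= 0)
  est <- estimates[!is.na(estimates$lat), , drop = FALSE]
  set.seed(seed)
  m <- nrow(est)
  lat0 <- rep(est$lat, each = n)
  lon0 <- rep(est$lon, each = n)
  km_per_deg <- pi / 180 * EARTH_RADIUS_KM
  lat <- lat0 + stats::rnorm(n * m, 0, sd_lat_km / km_per_deg)
  lon <- lon0 + stats::rnorm(n * m, 0,
                             sd_lon_km / (km_per_deg * cos(lat0 * pi / 180)))
  out <- data.frame(lon = lon, lat = lat,
                    source_row = rep(seq_len(m), each = n))
  out$on_land <- if (is.null(is_land)) FALSE else is_land(out$lon, out$lat)
  out
}

#' Kernel utilisation distribution on a grid
#'
#' Isotropic Gaussian kernel density on the projected plane with fixed
#' bandwidth `h_km`, evaluated at cell centres and renormalised to sum
#' to 1. If more than `edge_tol` of the theoretical mass falls outside
#' the grid, the grid is expanded automatically (with a warning).
#'
#' @param points Data frame or matrix of `lon`, `lat`.
#' @param h_km Bandwidth (km), > 0.
#' @param grid Optional `ir_grid`; default covers the points plus a
#'   3-bandwidth margin.
#' @param cell_km Cell size when building a default grid.
#' @param edge_tol Maximum tolerated off-grid mass before expansion.
#' @return Object of class `ir_ud`: `grid`, `p` (nx x ny masses summing
#'   to 1), `provenance` list.
#' @export
kde_ud <- function(points, h_km, grid = NULL, cell_km = 25,
                   edge_tol = 0.01) {
  stopifnot(h_km > 0)
  pts <- as.data.frame(points)[, 1:2]
  if (nrow(pts) < 1) stop("kde_ud: need at least one point")
  if (is.null(grid))
    grid <- ud_grid_for_points(pts, cell_km, margin_km = 3 * h_km)
  xy <- polar_xy(pts[[1]], pts[[2]])
  for (attempt in 1:4) {
    xc <- grid_xc(grid); yc <- grid_yc(grid)
    # Separable Gaussian kernels: cell mass ~ product of axis densities.
    Kx <- outer(xc, xy[, "x"], function(a, b)
      stats::dnorm(a, b, h_km)) * grid$cell_km
    Ky <- outer(yc, xy[, "y"], function(a, b)
      stats::dnorm(a, b, h_km)) * grid$cell_km
    p <- (Kx %*% t(Ky))  # sum over points of product kernels
    if (sum(p) == 0) {
      # bandwidth far below cell size: fall back to cell-count masses
      idx <- grid_cell_index(grid, xy[, "x"], xy[, "y"])
      p <- matrix(0, grid$nx, grid$ny)
      for (r in which(idx[, "ix"] > 0))
        p[idx[r, "ix"], idx[r, "iy"]] <- p[idx[r, "ix"], idx[r, "iy"]] + 1
      break
    }
    total <- sum(p) / nrow(pts)
    if (1 - total <= edge_tol) break
    warning("kde_ud: >", 100 * edge_tol,
            "% of kernel mass off-grid; expanding grid")
    grid <- make_grid(grid$x0 - 3 * h_km, grid$y0 - 3 * h_km,
                      grid$nx + ceiling(6 * h_km / grid$cell_km),
                      grid$ny + ceiling(6 * h_km / grid$cell_km),
                      grid$cell_km)
  }
  p <- p / sum(p)
  structure(list(grid = grid, p = p,
                 provenance = list(method = "kde", h_km = h_km,
                                   n_points = nrow(pts))),
            class = "ir_ud")
}

#' @export
print.ir_ud <- function(x, ...) {
  cat(sprintf("<ir_ud: %d x %d cells of %g km, method %s, h = %s km>\n",
              x$grid$nx, x$grid$ny, x$grid$cell_km,
              x$provenance$method,
              format(x$provenance$h_km %||% NA)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ad-hoc smoothing-parameter selection
#'
#' Returns the smallest candidate bandwidth for which, in every stage,
#' the population 95% (general foraging area) region consists of at most
#' `max_polygons` 8-connected polygons. If no candidate qualifies the
#' largest is returned with a warning.
#'
#' @param point_sets A list (stages) of lists (birds) of `lon`/`lat`
#'   data frames.
#' @param h_candidates Ascending candidate bandwidths (km).
#' @param level Cumulative-UD level defining the region (default 0.95).
#' @param max_polygons Maximum allowed polygon count (default 2).
#' @param cell_km Grid cell size (default 25 km).
#' @return Selected bandwidth (km), with attribute `polygon_counts`.
#' @export
select_smoothing <- function(point_sets, h_candidates, level = 0.95,
                             max_polygons = 2, cell_km = 25) {
  if (length(h_candidates) == 0) stop("select_smoothing: no candidates")
  if (is.unsorted(h_candidates)) stop("select_smoothing: candidates must ascend")
  all_pts <- do.call(rbind, lapply(point_sets, function(stage)
    do.call(rbind, lapply(stage, function(b) as.data.frame(b)[, 1:2]))))
  counts <- matrix(NA_integer_, length(h_candidates), length(point_sets))
  for (ih in seq_along(h_candidates)) {
    h <- h_candidates[ih]
    grid <- ud_grid_for_points(all_pts, cell_km, margin_km = 3 * h)
    ok <- TRUE
    for (is_ in seq_along(point_sets)) {
      uds <- lapply(point_sets[[is_]], kde_ud, h_km = h, grid = grid)
      pop <- population_ud(uds)
      reg <- ud_region(pop, level)
      counts[ih, is_] <- reg$n_polygons
      if (reg$n_polygons > max_polygons) ok <- FALSE
    }
    if (ok) {
      out <- h
      attr(out, "polygon_counts") <- counts[seq_len(ih), , drop = FALSE]
      return(out)
    }
  }
  warning("select_smoothing: no candidate bandwidth gave <= ",
          max_polygons, " polygons; returning the largest")
  out <- h_candidates[length(h_candidates)]
  attr(out, "polygon_counts") <- counts
  out
}

#' Autocorrelation-adjusted KDE for GPS foraging locations
#'
#' Kernel UD whose bandwidth accounts for serial autocorrelation of
#' regularly sampled positions: an exponential position-autocorrelation
#' timescale tau is fitted to the empirical lag correlation of the
#' coordinates, the effective sample size is
#' `N_eff = N * dt / (dt + 2 * tau)` clipped to `[2, N]`, and the
#' Gaussian reference-rule bandwidth `sigma * N_eff^(-1/6)` is applied.
#' This is an approximation to autocorrelated kernel density estimation,
#' recorded as such in the provenance; it is not the ctmm estimator.
#'
#' @param fixes Data frame with `timestamp`, `lon`, `lat`, regular
#'   sampling; >= 10 fixes.
#' @param grid,cell_km As in [kde_ud()].
#' @param max_lag Maximum lag (in sampling steps) used in the tau fit.
#' @return An `ir_ud` with provenance method `"gps_akde_approx"`, plus
#'   `tau_h`, `n_eff` and `h_km` recorded.
#' @export
autocorr_kde_ud <- function(fixes, grid = NULL, cell_km = 5, max_lag = 30) {
  if (nrow(fixes) < 10) stop("autocorr_kde_ud: need >= 10 fixes")
  xy <- polar_xy(fixes$lon, fixes$lat)
  dt_h <- stats::median(diff(as.numeric(fixes$timestamp))) / 3600
  n <- nrow(fixes)
  tau_h <- tryCatch({
    acfs <- sapply(list(xy[, "x"], xy[, "y"]), function(z) {
      a <- stats::acf(z, lag.max = min(max_lag, n - 2), plot = FALSE,
                      demean = TRUE)$acf[-1]
      a
    })
    a <- rowMeans(acfs)
    # leading run of lags with correlation clearly above noise
    use <- seq_len(max(which(cumsum(a <= 0.2) == 0), 0))
    if (length(use) < 1) stop("no usable lags")
    # exponential decay rho(k) = exp(-k*dt/tau): least squares of
    # log rho on lag through the origin
    lk <- log(a[use])
    slope <- sum(use * lk) / sum(use^2)   # log rho = slope * k
    tau <- -dt_h / slope
    if (!is.finite(tau) || tau <= 0) stop("tau not identifiable")
    tau
  }, error = function(e) NA_real_)
  if (is.na(tau_h)) {
    warning("autocorr_kde_ud: tau not identifiable; using N_eff = N")
    n_eff <- n
    tau_h <- 0
  } else {
    n_eff <- min(max(n * dt_h / (dt_h + 2 * tau_h), 2), n)
  }
  sigma <- sqrt((stats::var(xy[, "x"]) + stats::var(xy[, "y"])) / 2)
  h <- max(sigma * n_eff^(-1 / 6), 1e-6)
  ud <- kde_ud(as.data.frame(fixes[, c("lon", "lat")]), h_km = h,
               grid = grid, cell_km = cell_km)
  ud$provenance <- list(method = "gps_akde_approx", h_km = h,
                        tau_h = tau_h, n_eff = n_eff, n_points = n)
  ud
}

#' Population mean utilisation distribution
#'
#' Unweighted per-cell mean of individual UDs on a common grid,
#' renormalised. Permutation-invariant in bird order.
#'
#' @param uds List of `ir_ud` on identical grids.
#' @return An `ir_ud` with combined provenance.
#' @export
population_ud <- function(uds) {
  stopifnot(length(uds) >= 1)
  g <- uds[[1]]$grid
  for (u in uds) if (!grid_same(u$grid, g))
    stop("population_ud: UDs are not on a common grid")
  p <- Reduce(`+`, lapply(uds, `[[`, "p")) / length(uds)
  p <- p / sum(p)
  structure(list(grid = g, p = p,
                 provenance = list(method = uds[[1]]$provenance$method,
                                   h_km = uds[[1]]$provenance$h_km,
                                   n_birds = length(uds))),
            class = "ir_ud")
}

#' Cumulative utilisation-distribution region
#'
#' The region containing the first `level` of the cumulative UD: cells
#' sorted by density descending, smallest prefix whose mass reaches the
#' level, with all density-tied cells included. Polygon count uses
#' 8-neighbour connectivity.
#'
#' @param ud An `ir_ud`.
#' @param level Level in (0, 1), e.g. 0.5 (core area) or 0.95.
#' @return Object of class `ir_ud_region`: `level`, `cells` (logical
#'   nx x ny), `area_km2`, `n_polygons`, `grid`.
#' @export
ud_region <- function(ud, level) {
  stopifnot(level > 0, level < 1)
  o <- order(ud$p, decreasing = TRUE)
  cum <- cumsum(ud$p[o])
  k <- which(cum >= level - 1e-12)[1]
  thr <- ud$p[o[k]]
  cells <- ud$p >= thr & ud$p > 0   # include ties at the threshold density
  structure(list(level = level, cells = cells,
                 area_km2 = sum(cells) * grid_cell_area(ud$grid),
                 n_polygons = count_components_8(cells),
                 grid = ud$grid),
            class = "ir_ud_region")
}

#' @export
print.ir_ud_region <- function(x, ...) {
  cat(sprintf("<ir_ud_region: %.0f%% level, %.0f km2 in %d polygon(s)>\n",
              100 * x$level, x$area_km2, x$n_polygons))
  invisible(x)
}
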