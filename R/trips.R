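# GPS track processing: splitting into central-place foraging trips,
# regularisation to a fixed time step via a continuous-time correlated
# random walk (CTCRW) state-space smoother, coast crossings and overland
# commute headings.

#' Split a GPS fix series into foraging trips
#'
#' A trip is the maximal segment between an exit from and the next entry
#' into a circular colony buffer. The last fix inside the buffer before
#' departure and the first after return are included, so trips begin and
#' end at the colony. Segments shorter than the minimum duration are
#' discarded.
#'
#' @param fixes Data frame with `timestamp` (POSIXct, increasing), `lon`,
#'   `lat` (and optionally `bird_id` and other columns, carried through).
#' @param colony List or one-row data frame with `lon`, `lat`.
#' @param radius_km Colony buffer radius (km), default 5.
#' @param min_duration_h Minimum trip duration (hours), default 2.
#' @return List of trip data frames, each with attributes `departure`,
#'   `return_time` and `trip_id`.
#' @export
split_trips <- function(fixes, colony, radius_km = 5, min_duration_h = 2) {
  stopifnot(!is.unsorted(as.numeric(fixes$timestamp)))
  d <- gc_dist_km(fixes$lon, fixes$lat, colony$lon, colony$lat)
  outside <- d > radius_km
  n <- nrow(fixes)
  trips <- list()
  i <- 1L
  while (i <= n) {
    if (!outside[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && outside[j + 1L]) j <- j + 1L
    lo <- max(1L, i - 1L)           # include last fix inside the buffer
    hi <- min(n, j + 1L)            # and the first after return
    dur_h <- as.numeric(fixes$timestamp[hi] - fixes$timestamp[lo],
                        units = "hours")
    if (dur_h >= min_duration_h) {
      tr <- fixes[lo:hi, , drop = FALSE]
      rownames(tr) <- NULL
      attr(tr, "departure") <- fixes$timestamp[lo]
      attr(tr, "return_time") <- fixes$timestamp[hi]
      attr(tr, "trip_id") <- length(trips) + 1L
      trips[[length(trips) + 1L]] <- tr
    }
    i <- j + 1L
  }
  trips
}

# CTCRW transition matrices for state (x, v) over time step dt:
# velocity is Ornstein-Uhlenbeck with reversion beta and noise sigma,
# position integrates velocity (Johnson et al.'s movement model).
ctcrw_mats <- function(dt, beta, sigma) {
  e1 <- exp(-beta * dt); e2 <- exp(-2 * beta * dt)
  F <- matrix(c(1, 0, (1 - e1) / beta, e1), 2, 2)
  qv <- sigma^2 / (2 * beta) * (1 - e2)
  qxv <- sigma^2 / (2 * beta^2) * (1 - 2 * e1 + e2)
  qx <- sigma^2 / beta^2 *
    (dt - 2 * (1 - e1) / beta + (1 - e2) / (2 * beta))
  Q <- matrix(c(qx, qxv, qxv, qv), 2, 2)
  list(F = F, Q = Q)
}

# Kalman filter + RTS smoother for one coordinate observed at times tt
# (positions y, observation sd tau); returns smoothed positions at times
# out_t (a superset union is formed internally). Used by regularize().
ctcrw_smooth_1d <- function(tt, y, out_t, beta, sigma, tau) {
  all_t <- sort(unique(c(tt, out_t)))
  m <- length(all_t)
  obs <- match(all_t, tt)
  xp <- vector("list", m); Pp <- vector("list", m)
  xf <- vector("list", m); Pf <- vector("list", m)
  v0 <- if (length(tt) > 1) (y[2] - y[1]) / max(tt[2] - tt[1], 1e-6) else 0
  x <- c(y[1], v0)
  P <- diag(c(1, max(1e-2, v0^2 + sigma^2 / (2 * beta))))
  Fs <- vector("list", m)
  for (k in seq_len(m)) {
    if (k == 1) {
      Fs[[k]] <- diag(2)
    } else {
      mats <- ctcrw_mats(all_t[k] - all_t[k - 1], beta, sigma)
      Fs[[k]] <- mats$F
      x <- mats$F %*% x
      P <- mats$F %*% P %*% t(mats$F) + mats$Q
    }
    xp[[k]] <- x; Pp[[k]] <- P
    if (!is.na(obs[k])) {
      S <- P[1, 1] + tau^2
      K <- P[, 1] / S
      x <- x + K * (y[obs[k]] - x[1])
      P <- P - outer(K, P[1, ])
      P <- (P + t(P)) / 2
    }
    xf[[k]] <- x; Pf[[k]] <- P
  }
  # RTS smoother
  xs <- xf; Ps <- Pf
  for (k in (m - 1):1) {
    if (m < 2) break
    G <- tryCatch(Pf[[k]] %*% t(Fs[[k + 1]]) %*% solve(Pp[[k + 1]]),
                  error = function(e) matrix(0, 2, 2))
    xs[[k]] <- xf[[k]] + G %*% (xs[[k + 1]] - xp[[k + 1]])
    Ps[[k]] <- Pf[[k]] + G %*% (Ps[[k + 1]] - Pp[[k + 1]]) %*% t(G)
  }
  pos <- vapply(xs, function(v) v[1], numeric(1))
  pos[match(out_t, all_t)]
}

# Negative log-likelihood of the CTCRW for both coordinates (shared
# beta/sigma), via the Kalman prediction-error decomposition.
ctcrw_nll <- function(logpar, tt, xx, yy, tau) {
  beta <- exp(logpar[1]); sigma <- exp(logpar[2])
  nll <- 0
  for (y in list(xx, yy)) {
    v0 <- (y[2] - y[1]) / max(tt[2] - tt[1], 1e-6)
    x <- c(y[1], v0)
    P <- diag(c(tau^2 + 1e-6, max(1e-2, sigma^2 / (2 * beta))))
    for (k in 2:length(tt)) {
      mats <- ctcrw_mats(tt[k] - tt[k - 1], beta, sigma)
      x <- mats$F %*% x
      P <- mats$F %*% P %*% t(mats$F) + mats$Q
      S <- P[1, 1] + tau^2
      if (!is.finite(S) || S <= 0) return(1e10)
      e <- y[k] - x[1]
      nll <- nll + 0.5 * (log(2 * pi * S) + e^2 / S)
      K <- P[, 1] / S
      x <- x + K * e
      P <- P - outer(K, P[1, ])
    }
  }
  if (!is.finite(nll)) 1e10 else nll
}

#' Regularise a trip to a fixed time step
#'
#' Predicts positions on an exact interval grid using a continuous-time
#' correlated random walk state-space model (integrated Ornstein-Uhlenbeck
#' velocity), with mean-reversion and diffusion parameters estimated per
#' trip by maximum likelihood; `method = "linear"` is a documented
#' fallback. Grid times that coincide exactly with an observed fix return
#' the observed position. Gaps longer than `max_gap_h` are bridged but the
#' affected grid fixes are flagged.
#'
#' @param trip Trip data frame (`timestamp`, `lon`, `lat`), >= 3 fixes.
#' @param interval_min Output interval in minutes (default 30).
#' @param method "crw" (default) or "linear".
#' @param max_gap_h Gap length (hours) beyond which interpolated fixes are
#'   flagged (default 4).
#' @param obs_error_km Observation error sd for the state-space model
#'   (km); default 0.02 (GPS-scale).
#' @return Data frame `timestamp`, `lon`, `lat`, `interpolated`,
#'   `gap_flag`; attribute `method`.
#' @export
regularize <- function(trip, interval_min = 30, method = c("crw", "linear"),
                       max_gap_h = 4, obs_error_km = 0.02) {
  method <- match.arg(method)
  if (nrow(trip) < 3) stop("regularize: need at least 3 fixes")
  tt <- as.numeric(trip$timestamp)
  stopifnot(!is.unsorted(tt, strictly = TRUE))
  step_s <- interval_min * 60
  grid_t <- seq(ceiling(tt[1] / step_s) * step_s,
                floor(tt[length(tt)] / step_s) * step_s, by = step_s)
  if (length(grid_t) == 0) stop("regularize: trip shorter than one interval")
  xy <- polar_xy(trip$lon, trip$lat)
  th <- (tt - tt[1]) / 3600   # hours, for conditioning
  gh <- (grid_t - tt[1]) / 3600
  if (all(grid_t %in% tt)) {
    # already regular: pass-through, no state-space fit needed
    hit0 <- match(grid_t, tt)
    out <- data.frame(
      timestamp = as.POSIXct(grid_t, tz = "UTC", origin = "1970-01-01"),
      lon = trip$lon[hit0], lat = trip$lat[hit0],
      interpolated = FALSE, gap_flag = FALSE)
    attr(out, "method") <- method
    return(out)
  }
  if (method == "linear" || nrow(trip) < 4) {
    gx <- stats::approx(th, xy[, "x"], xout = gh, rule = 2)$y
    gy <- stats::approx(th, xy[, "y"], xout = gh, rule = 2)$y
  } else {
    fit <- stats::optim(c(log(1), log(5)), ctcrw_nll, tt = th,
                        xx = xy[, "x"], yy = xy[, "y"], tau = obs_error_km,
                        method = "Nelder-Mead",
                        control = list(maxit = 200))
    beta <- exp(fit$par[1]); sigma <- exp(fit$par[2])
    gx <- ctcrw_smooth_1d(th, xy[, "x"], gh, beta, sigma, obs_error_km)
    gy <- ctcrw_smooth_1d(th, xy[, "y"], gh, beta, sigma, obs_error_km)
  }
  # Exact pass-through where grid times coincide with observations.
  hit <- match(grid_t, tt)
  gx[!is.na(hit)] <- xy[hit[!is.na(hit)], "x"]
  gy[!is.na(hit)] <- xy[hit[!is.na(hit)], "y"]
  # Flag grid fixes inside long observation gaps.
  gap_flag <- rep(FALSE, length(grid_t))
  gaps <- diff(tt) / 3600
  long <- which(gaps > max_gap_h)
  for (g in long)
    gap_flag[grid_t > tt[g] & grid_t < tt[g + 1]] <- TRUE
  ll <- polar_lonlat(gx, gy)
  out <- data.frame(
    timestamp = as.POSIXct(grid_t, tz = "UTC", origin = "1970-01-01"),
    lon = ll[, "lon"], lat = ll[, "lat"],
    interpolated = is.na(hit), gap_flag = gap_flag)
  attr(out, "method") <- method
  out
}

#' Coast crossings and overland commute headings of a trip
#'
#' `s1` is the first intersection of the outbound path with the coastline
#' (land-to-sea transition, refined by bisection along the segment), `s2`
#' the last intersection of the inbound path (sea-to-land). `theta_out` is
#' the initial great-circle bearing from the colony to the first at-sea
#' fix, `theta_in` the bearing from the last at-sea fix to the colony.
#'
#' @param trip Trip data frame (`timestamp`, `lon`, `lat`).
#' @param domain An `ir_domain` (provides `is_land`).
#' @param colony List with `lon`, `lat`; defaults to the domain's first
#'   colony.
#' @return List `s1`, `s2` (named lon/lat vectors or `NULL`), `theta_out`,
#'   `theta_in` (deg or `NA`), `at_sea` (logical vector), `flag`.
#' @export
coast_crossings <- function(trip, domain, colony = NULL) {
  if (is.null(colony)) colony <- as.list(domain$colonies[1, ])
  at_sea <- !domain$is_land(trip$lon, trip$lat)
  if (!any(at_sea))
    return(list(s1 = NULL, s2 = NULL, theta_out = NA_real_,
                theta_in = NA_real_, at_sea = at_sea, flag = "never_at_sea"))
  refine <- function(p_land, p_sea) {
    for (k in 1:25) {
      mid <- (p_land + p_sea) / 2
      if (domain$is_land(mid[1], mid[2])) p_land <- mid else p_sea <- mid
    }
    c(lon = (p_land[1] + p_sea[1]) / 2, lat = (p_land[2] + p_sea[2]) / 2)
  }
  first_sea <- which(at_sea)[1]
  last_sea <- which(at_sea)[length(which(at_sea))]
  s1 <- if (first_sea > 1)
    refine(c(trip$lon[first_sea - 1], trip$lat[first_sea - 1]),
           c(trip$lon[first_sea], trip$lat[first_sea]))
  else c(lon = trip$lon[1], lat = trip$lat[1])
  s2 <- if (last_sea < nrow(trip))
    refine(c(trip$lon[last_sea + 1], trip$lat[last_sea + 1]),
           c(trip$lon[last_sea], trip$lat[last_sea]))
  else c(lon = trip$lon[nrow(trip)], lat = trip$lat[nrow(trip)])
  list(s1 = s1, s2 = s2,
       theta_out = gc_bearing(colony$lon, colony$lat,
                              trip$lon[first_sea], trip$lat[first_sea]),
       theta_in = gc_bearing(trip$lon[last_sea], trip$lat[last_sea],
                             colony$lon, colony$lat),
       at_sea = at_sea, flag = NA_character_)
}
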