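# Independent oracles and shared fixtures. These deliberately avoid the
# package's own code paths: the Dijkstra oracle is a plain array-based
# implementation, the solar oracle a different published algorithm, and
# the forward-likelihood oracle enumerates all state paths.

# Brute-force Dijkstra over a passable mask with geodesic edge weights,
# linear min-selection; independent of igraph and of the package.
brute_dijkstra <- function(surface, origin_cell) {
  g <- surface$grid
  nx <- g$nx; ny <- g$ny
  pass <- surface$passable
  ll <- surface$centres_lonlat
  offs <- if (surface$connectivity == 16) {
    rbind(c(1,0),c(-1,0),c(0,1),c(0,-1),c(1,1),c(1,-1),c(-1,1),c(-1,-1),
          c(1,2),c(2,1),c(-1,2),c(-2,1),c(1,-2),c(2,-1),c(-1,-2),c(-2,-1))
  } else {
    rbind(c(1,0),c(-1,0),c(0,1),c(0,-1),c(1,1),c(1,-1),c(-1,1),c(-1,-1))
  }
  dist <- matrix(Inf, nx, ny)
  done <- matrix(FALSE, nx, ny)
  dist[origin_cell[1], origin_cell[2]] <- 0
  repeat {
    u <- which(!done & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    ui <- ((u - 1) %% nx) + 1; uj <- ((u - 1) %/% nx) + 1
    for (k in seq_len(nrow(offs))) {
      vi <- ui + offs[k, 1]; vj <- uj + offs[k, 2]
      if (vi < 1 || vi > nx || vj < 1 || vj > ny) next
      if (!pass[vi, vj] || done[vi, vj]) next
      w <- gc_dist_km(ll[u, "lon"], ll[u, "lat"],
                      ll[(vj - 1) * nx + vi, "lon"],
                      ll[(vj - 1) * nx + vi, "lat"])
      if (dist[u] + w < dist[vi, vj]) dist[vi, vj] <- dist[u] + w
    }
  }
  dist
}

# Solar elevation via the NOAA/Spencer Fourier-series formulas: an
# algorithm distinct from the package's ephemeris.
solar_elevation_noaa <- function(lat, lon, time) {
  t <- as.POSIXct(time, tz = "UTC")
  doy <- as.integer(format(t, "%j"))
  hour <- as.numeric(t - trunc(t, "days"), units = "hours")
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour * 60 + eqtime + 4 * lon
  ha <- (tst / 4 - 180) * pi / 180
  phi <- lat * pi / 180
  asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)) * 180 / pi
}

# Exact HMM likelihood by enumerating every state path (sequences <= ~8).
enumerate_loglik <- function(allprobs, trans, delta) {
  n <- nrow(allprobs); N <- ncol(allprobs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- delta[s[1]] * allprobs[1, s[1]]
    if (n > 1) for (t in 2:n)
      p <- p * trans[s[t - 1], s[t]] * allprobs[t, s[t]]
    tot <- tot + p
  }
  log(tot)
}

# All-sea cost surface in the polar cap (low projection distortion), used
# by several distance tests.
all_sea_surface <- function(nx = 40, ny = 40, cell_km = 25,
                            connectivity = 16, x0 = 0, y0 = -1600) {
  dom <- structure(list(is_land = function(lon, lat)
    rep(FALSE, length(lon))), class = "ir_domain")
  build_cost_surface(dom, grid = icerange:::make_grid(x0, y0, nx, ny,
                                                      cell_km),
                     connectivity = connectivity)
}

# Random masked surface: smooth blobby land, guaranteed passable origin.
random_mask_surface <- function(seed, nx = 40, ny = 40, cell_km = 25,
                                connectivity = 16) {
  set.seed(seed)
  base <- matrix(stats::rnorm(nx * ny), nx, ny)
  sm <- base
  for (k in 1:3) {
    sm <- (sm +
             rbind(sm[-1, ], sm[nx, ]) + rbind(sm[1, ], sm[-nx, ]) +
             cbind(sm[, -1], sm[, ny]) + cbind(sm[, 1], sm[, -ny])) / 5
  }
  pass <- sm > stats::quantile(sm, 0.35)
  surf <- all_sea_surface(nx, ny, cell_km, connectivity)
  surf$passable <- pass
  surf
}

# Small synthetic light series for a fixed position over a date range.
make_light <- function(lon, lat, from, to, by_min = 5) {
  times <- seq(as.POSIXct(from, tz = "UTC"), as.POSIXct(to, tz = "UTC"),
               by = by_min * 60)
  elev <- solar_position(lat, lon, times)
  data.frame(timestamp = times,
             light = icerange:::light_from_elevation(elev))
}

# Light threshold whose crossing corresponds to a given sun angle under
# the generator's light transfer function.
light_threshold_for <- function(sun_angle) {
  icerange:::light_from_elevation(sun_angle)
}

# Shared small study system for the slower end-to-end tests (built once).
shared_domain <- local({
  dom <- NULL
  function() {
    if (is.null(dom)) dom <<- generate_domain(seed = 11)
    dom
  }
})
shared_season <- local({
  season <- NULL
  function() {
    if (is.null(season)) season <<- generate_sic_season(shared_domain(),
                                                        seed = 11)
    season
  }
})
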