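test_that("location augmentation: limits, counts and sampling sds", {
  est <- data.frame(lon = c(0, 10), lat = c(-60, -65))
  # sd -> 0: all draws coincide with the estimates
  a0 <- augment_gls_locations(est, sd_lat_km = 1e-12, sd_lon_km = 1e-12,
                              n = 10, seed = 1)
  expect_equal(nrow(a0), 20)
  expect_equal(a0$lon, rep(est$lon, each = 10), tolerance = 1e-9)
  # counts: n = 100 x 50 estimates -> 5000 points
  est50 <- data.frame(lon = runif(50, -5, 5), lat = runif(50, -65, -60))
  expect_equal(nrow(augment_gls_locations(est50, n = 100, seed = 1)), 5000)
  # sampled sds within 5% of nominal at n = 10000
  one <- data.frame(lon = 0, lat = -62)
  big <- augment_gls_locations(one, sd_lat_km = 200, sd_lon_km = 150,
                               n = 10000, seed = 2)
  km_per_deg <- pi / 180 * 6371
  expect_lt(abs(sd(big$lat) * km_per_deg - 200) / 200, 0.05)
  expect_lt(abs(sd(big$lon) * km_per_deg * cos(-62 * pi / 180) - 150) /
              150, 0.05)
})

test_that("kernel UD: normalisation, symmetry and peak placement", {
  one <- data.frame(lon = 5, lat = -64)
  ud <- kde_ud(one, h_km = 100, cell_km = 25)
  expect_equal(sum(ud$p), 1, tolerance = 1e-12)
  peak <- which(ud$p == max(ud$p), arr.ind = TRUE)
  ctr <- icerange:::grid_cell_of_lonlat(ud$grid, 5, -64)
  expect_equal(unname(peak[1, ]), unname(c(ctr[1, "ix"], ctr[1, "iy"])))
  # two distant identical points on a mirror-symmetric grid: bimodal
  # with exactly mirrored masses
  pp <- polar_lonlat(c(-300, 300), c(-2200, -2200))
  two <- data.frame(lon = pp[, "lon"], lat = pp[, "lat"])
  g2 <- icerange:::make_grid(-20 * 25, -2400, 40, 16, 25)
  ud2 <- kde_ud(two, h_km = 50, grid = g2)
  expect_lt(max(abs(ud2$p - ud2$p[rev(seq_len(40)), ])), 1e-9)
  expect_gt(sum(ud2$p > 0.5 * max(ud2$p)), 1)  # two separated modes
})

test_that("error-propagated KDE converges to plain KDE as sd -> 0, n = 1", {
  pts <- data.frame(lon = c(2, 4, 3), lat = c(-63, -64, -65))
  grid <- ud_grid_for_points(pts, 25, 400)
  plain <- kde_ud(pts, h_km = 100, grid = grid)
  aug <- augment_gls_locations(pts, sd_lat_km = 1e-12, sd_lon_km = 1e-12,
                               n = 1, seed = 1)
  prop <- kde_ud(aug[, c("lon", "lat")], h_km = 100, grid = grid)
  expect_lt(max(abs(plain$p - prop$p)), 1e-12)
})

test_that("UD regions: cumulative level, ties, nesting and minimality", {
  # uniform UD over 100 cells: 50% region has exactly 50 cells (all tied
  # cells included would be all 100 -- construct strictly unequal masses)
  g <- icerange:::make_grid(0, -1600, 10, 10, 25)
  ud_u <- structure(list(grid = g, p = matrix(1 / 100, 10, 10),
                         provenance = list(method = "kde")),
                    class = "ir_ud")
  r <- ud_region(ud_u, 0.5)
  expect_equal(r$area_km2, 100 * 625)  # all cells tie at the threshold
  set.seed(7)
  for (k in 1:20) {
    p <- matrix(rexp(100), 10, 10); p <- p / sum(p)
    ud <- structure(list(grid = g, p = p,
                         provenance = list(method = "kde")),
                    class = "ir_ud")
    r50 <- ud_region(ud, 0.5); r95 <- ud_region(ud, 0.95)
    expect_true(all(r95$cells[r50$cells]))          # nesting
    expect_gte(sum(p[r50$cells]), 0.5)              # reaches the level
    # minimality: dropping the least-dense included cell goes below level
    dens <- p[r50$cells]
    expect_lt(sum(dens) - min(dens), 0.5)
  }
})

test_that("population UD: idempotence, arithmetic, permutation invariance", {
  g <- icerange:::make_grid(0, -1600, 6, 6, 25)
  mk <- function(p) structure(list(grid = g, p = p / sum(p),
                                   provenance = list(method = "kde")),
                              class = "ir_ud")
  set.seed(1)
  u1 <- mk(matrix(rexp(36), 6, 6)); u2 <- mk(matrix(rexp(36), 6, 6))
  u3 <- mk(matrix(rexp(36), 6, 6))
  expect_equal(population_ud(list(u1, u1))$p, u1$p, tolerance = 1e-12)
  pop <- population_ud(list(u1, u2, u3))
  expect_equal(sum(pop$p), 1, tolerance = 1e-12)
  pop2 <- population_ud(list(u3, u1, u2))
  expect_equal(pop$p, pop2$p, tolerance = 1e-14)
  # two disjoint single-cell UDs -> 0.5 each
  a <- matrix(0, 6, 6); a[2, 2] <- 1
  b <- matrix(0, 6, 6); b[5, 5] <- 1
  pab <- population_ud(list(mk(a), mk(b)))
  expect_equal(pab$p[2, 2], 0.5)
  expect_equal(pab$p[5, 5], 0.5)
  g2 <- icerange:::make_grid(0, -1600, 7, 6, 25)
  u4 <- structure(list(grid = g2, p = matrix(1 / 42, 7, 6),
                       provenance = list(method = "kde")),
                  class = "ir_ud")
  expect_error(population_ud(list(u1, u4)), "common grid")
})

test_that("bandwidth selection agrees with an exhaustive scan", {
  set.seed(3)
  # two clusters ~500 km apart
  b1 <- data.frame(lon = rnorm(40, 0, 0.6), lat = rnorm(40, -63, 0.3))
  b2 <- data.frame(lon = rnorm(40, 10, 0.6), lat = rnorm(40, -63, 0.3))
  sets <- list(stage1 = list(b1, b2))
  cands <- c(25, 50, 100, 150, 200, 300, 400)
  h <- select_smoothing(sets, cands, level = 0.95, max_polygons = 2,
                        cell_km = 25)
  # exhaustive oracle: recompute polygon counts for every candidate
  all_pts <- rbind(b1, b2)
  ok <- vapply(cands, function(hh) {
    grid <- ud_grid_for_points(all_pts, 25, 3 * hh)
    uds <- lapply(list(b1, b2), kde_ud, h_km = hh, grid = grid)
    ud_region(population_ud(uds), 0.95)$n_polygons <= 2
  }, logical(1))
  expect_equal(as.numeric(h), cands[which(ok)[1]])
  # single tight cluster: smallest candidate wins
  tight <- list(list(data.frame(lon = rnorm(30, 5, 0.2),
                                lat = rnorm(30, -64, 0.1))))
  expect_equal(as.numeric(select_smoothing(tight, cands)), 25)
  # unbounded polygon count: vacuous constraint
  expect_equal(as.numeric(select_smoothing(sets, cands,
                                           max_polygons = Inf)), 25)
  expect_error(select_smoothing(sets, numeric(0)), "candidates")
})

test_that("autocorrelation-adjusted bandwidth responds to tau", {
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  # OU-process simulation with known timescale
  sim_ou <- function(n, tau_h, dt_h = 0.5, sd_km = 60, seed = 1) {
    set.seed(seed)
    a <- exp(-dt_h / tau_h)
    x <- numeric(n); y <- numeric(n)
    for (k in 2:n) {
      x[k] <- a * x[k - 1] + rnorm(1, 0, sd_km * sqrt(1 - a^2))
      y[k] <- a * y[k - 1] + rnorm(1, 0, sd_km * sqrt(1 - a^2))
    }
    xy0 <- polar_xy(5, -64)
    ll <- polar_lonlat(xy0[1, "x"] + x, xy0[1, "y"] + y)
    data.frame(timestamp = t0 + (seq_len(n) - 1) * dt_h * 3600,
               lon = ll[, "lon"], lat = ll[, "lat"])
  }
  fx <- sim_ou(1000, tau_h = 5)
  ud <- autocorr_kde_ud(fx, cell_km = 25)
  expect_lt(abs(ud$provenance$tau_h - 5) / 5, 0.25)
  expect_lt(ud$provenance$n_eff, 1000 / 5)
  expect_equal(ud$provenance$method, "gps_akde_approx")
  expect_equal(sum(ud$p), 1, tolerance = 1e-9)
  # near-independent fixes: N_eff ~ N, bandwidth ~ plain reference rule
  fx2 <- sim_ou(500, tau_h = 0.01, seed = 2)
  ud2 <- suppressWarnings(autocorr_kde_ud(fx2, cell_km = 25))
  expect_gt(ud2$provenance$n_eff, 450)
  xy <- polar_xy(fx2$lon, fx2$lat)
  href <- sqrt((var(xy[, "x"]) + var(xy[, "y"])) / 2) *
    ud2$provenance$n_eff^(-1 / 6)
  expect_equal(ud2$provenance$h_km, href, tolerance = 1e-9)
  # near-perfect autocorrelation: N_eff driven toward its floor and the
  # bandwidth inflated relative to the naive reference rule
  fx3 <- sim_ou(200, tau_h = 500, seed = 3)
  # the inflated bandwidth can exceed the initial grid margin, triggering
  # the documented expand-with-warning path
  ud3 <- suppressWarnings(autocorr_kde_ud(fx3, cell_km = 25))
  expect_lt(ud3$provenance$n_eff, 20)
  xy3 <- polar_xy(fx3$lon, fx3$lat)
  h_naive <- sqrt((var(xy3[, "x"]) + var(xy3[, "y"])) / 2) * 200^(-1 / 6)
  expect_gt(ud3$provenance$h_km, h_naive)
})
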