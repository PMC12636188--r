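test_that("cost surface rasterisation matches the land predicate per cell", {
  dom <- shared_domain()
  surf <- build_cost_surface(dom, cell_km = 25)
  ll <- surf$centres_lonlat
  oracle <- !dom$is_land(ll[, "lon"], ll[, "lat"])
  expect_identical(as.vector(surf$passable), oracle)
  # all-sea toy domain: everything passable
  expect_true(all(all_sea_surface(10, 10)$passable))
  all_land <- structure(list(is_land = function(lon, lat)
    rep(TRUE, length(lon))), class = "ir_domain")
  expect_error(build_cost_surface(all_land,
                                  grid = icerange:::make_grid(0, -1600,
                                                              5, 5, 25)),
               "no passable")
})

test_that("distance field equals the brute-force Dijkstra oracle", {
  for (seed in c(1, 7, 23, 40, 77)) {
    surf <- random_mask_surface(seed, nx = 25, ny = 25,
                                connectivity = if (seed %% 2) 16 else 8)
    origin <- which(surf$passable, arr.ind = TRUE)[1, ]
    f <- distance_field(surf, c(origin[1], origin[2]),
                        origin_is_cell = TRUE)
    oracle <- brute_dijkstra(surf, origin)
    expect_equal(f$dist_km, oracle, tolerance = 1e-9)
  }
})

test_that("distance field respects geometry bounds and channels", {
  # straight 1-cell channel: distance = cells x cell size along the axis
  dom <- structure(list(is_land = function(lon, lat)
    rep(FALSE, length(lon))), class = "ir_domain")
  g <- icerange:::make_grid(0, -1500, 30, 3, 25)
  surf <- build_cost_surface(dom, grid = g, connectivity = 8)
  surf$passable[, c(1, 3)] <- FALSE
  f <- distance_field(surf, c(1, 2), origin_is_cell = TRUE)
  steps <- vapply(2:30, function(i)
    gc_dist_km(surf$centres_lonlat[(2 - 1) * 30 + i - 1, "lon"],
               surf$centres_lonlat[(2 - 1) * 30 + i - 1, "lat"],
               surf$centres_lonlat[(2 - 1) * 30 + i, "lon"],
               surf$centres_lonlat[(2 - 1) * 30 + i, "lat"]),
    numeric(1))
  expect_equal(f$dist_km[30, 2], sum(steps), tolerance = 1e-9)
  # lower bound: never below great circle; 16-neighbour all-sea ratio
  surf2 <- all_sea_surface(35, 35, y0 = -1500)
  f2 <- distance_field(surf2, c(18, 18), origin_is_cell = TRUE)
  ll <- surf2$centres_lonlat
  oi <- (18 - 1) * 35 + 18
  gc <- gc_dist_km(ll[oi, "lon"], ll[oi, "lat"], ll[, "lon"], ll[, "lat"])
  ratio <- as.vector(f2$dist_km) / gc
  ratio <- ratio[gc > 100]
  expect_true(all(as.vector(f2$dist_km) >= gc - 1e-6))
  expect_lte(max(ratio), 1.028)
  expect_lte(median(ratio), 1.0196 + 0.01)
  # impassable origin
  surf3 <- random_mask_surface(2, nx = 15, ny = 15)
  blocked <- which(!surf3$passable, arr.ind = TRUE)[1, ]
  expect_error(distance_field(surf3, c(blocked[1], blocked[2]),
                              origin_is_cell = TRUE), "impassable")
})

test_that("biological distance follows its defining identity", {
  dom <- shared_domain()
  surf <- build_cost_surface(dom, cell_km = 25)
  colony <- as.list(dom$colonies[1, ])
  cl <- dom$coast_lat_fun(0)
  s1 <- c(lon = 0, lat = cl + 0.15)
  s2 <- c(lon = 5, lat = dom$coast_lat_fun(5) + 0.15)
  x <- data.frame(lon = c(2, 8, -5), lat = c(-64, -63, -65))
  bd <- biological_distance(colony, x, s1, s2, surf)
  expect_equal(bd$d_x,
               (bd$d_c_s1 + bd$d_s1_x + bd$d_x_s2 + bd$d_s2_c) / 2,
               tolerance = 1e-12)
  expect_true(all(bd[, 1:5] >= 0))
  # x = s1 = s2: sea legs vanish, d_x reduces to the overland leg
  bd0 <- biological_distance(colony, data.frame(lon = s1["lon"],
                                                lat = s1["lat"]),
                             s1, s1, surf)
  expect_lt(bd0$d_s1_x, surf$grid$cell_km)  # same cell
  expect_equal(bd0$d_x, bd0$d_c_s1, tolerance = surf$grid$cell_km)
  # coastal colony in open sea: d_x ~ great-circle within the
  # connectivity bound
  sea_colony <- list(lon = 0, lat = -63)
  p <- c(lon = 0, lat = -60)
  bd2 <- biological_distance(sea_colony, data.frame(lon = p["lon"],
                                                    lat = p["lat"]),
                             c(0, -63), c(0, -63), surf)
  gc <- gc_dist_km(0, -63, 0, -60)
  expect_lt(bd2$d_x / gc, 1.03 + 25 / gc)
  expect_gt(bd2$d_x / gc, 0.95)
})

test_that("a peninsula forces the biological distance above the beeline", {
  # zonal coast with a tall promontory between the crossing and the target
  shelf <- data.frame(lon = 5, half_width_deg = 1.5, north_km = 500)
  dom <- generate_domain(domain_config(shelves = shelf,
                                       coast_noise_deg = 0), seed = 3)
  surf <- build_cost_surface(dom, cell_km = 25)
  colony <- as.list(dom$colonies[1, ])
  s1 <- c(lon = 1, lat = dom$coast_lat_fun(1) + 0.15)
  x <- data.frame(lon = 9, lat = dom$coast_lat_fun(9) + 0.3)
  bd <- biological_distance(colony, x, s1, s1, surf)
  beeline <- gc_dist_km(colony$lon, colony$lat, x$lon, x$lat)
  expect_gt(bd$d_x, beeline)
})

test_that("GLS crossing assumption takes coastline medians", {
  dom <- shared_domain()
  cr <- data.frame(s1_lon = c(-2, 0, 4), s2_lon = c(1, 3, 5))
  res <- gls_crossing_assumption(cr, dom$coast_lat_fun)
  expect_equal(unname(res$s1["lon"]), 0)
  expect_equal(unname(res$s2["lon"]), 3)
  expect_equal(unname(res$s1["lat"]), dom$coast_lat_fun(0))
  one <- gls_crossing_assumption(data.frame(s1_lon = 2, s2_lon = 2),
                                 dom$coast_lat_fun)
  expect_equal(unname(one$s1["lon"]), 2)
  expect_error(gls_crossing_assumption(data.frame()[0, ],
                                       dom$coast_lat_fun), "crossings")
})

test_that("range summaries use linear-interpolation quantiles", {
  rs <- range_summary(c(100, 200, 300))
  expect_equal(rs$d50, 200)
  expect_equal(rs$d95, unname(quantile(c(100, 200, 300), 0.95)))
  expect_equal(rs$dmax, 300)
  one <- range_summary(42)
  expect_equal(c(one$d50, one$d95, one$dmax), c(42, 42, 42))
  grp <- range_summary(c(1, 2, 3, Inf, Inf),
                       group = c("a", "a", "a", "b", "b"))
  expect_true(grp$empty[grp$group == "b"])
  expect_equal(grp$n[grp$group == "a"], 3)
  expect_true(all(!is.na(grp$d50[!grp$empty])))
  expect_true(all(grp$d50 <= grp$d95 & grp$d95 <= grp$dmax, na.rm = TRUE))
})

test_that("projected range contours are nested and bounded below", {
  dom <- shared_domain()
  surf <- cache_surface_graph(build_cost_surface(dom, cell_km = 25))
  colony <- as.list(dom$colonies[1, ])
  pr <- project_ranges(colony, surf, c(500, 1500), dom$is_land)
  # s1 lies on the coast along the 317-degree ray
  expect_lt(abs(icerange:::angle_diff(
    gc_bearing(colony$lon, colony$lat, pr$s1["lon"], pr$s1["lat"]), 317)),
    2)
  # nesting: every sea cell within 500 km is within 1500 km
  expect_true(all(pr$field$dist_km[pr$field$dist_km <= 500] <= 1500))
  # 500-contour vertices sit strictly inside the 1500-contour's distances
  lv <- vapply(pr$contours, function(cc) cc$level_km[1], numeric(1))
  expect_true(any(lv == 500) && any(lv == 1500))
  # Eq. 3 lower bound: the overland legs alone
  overland <- (gc_dist_km(colony$lon, colony$lat,
                          pr$s1["lon"], pr$s1["lat"]) +
                 gc_dist_km(pr$s2["lon"], pr$s2["lat"],
                            colony$lon, colony$lat)) / 2
  expect_gte(min(pr$field$dist_km, na.rm = TRUE), overland - 1e-6)
})
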