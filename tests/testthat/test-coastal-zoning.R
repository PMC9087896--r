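test_that("distance to the coast is the perpendicular distance in km", {
  coast <- straight_coast(0)
  pts <- tibble::tibble(x = c(0, 30000, 12500), y = c(0, 0, 77777))
  out <- distance_to_coast(pts, coast)
  expect_equal(out$dist_km, c(0, 30, 12.5))
  # a vertex itself is at distance zero
  bent <- coastline(c(0, 1000, 1500), c(0, 2000, 5000))
  on_vertex <- tibble::tibble(x = 1000, y = 2000)
  expect_equal(distance_to_coast(on_vertex, bent)$dist_km, 0)
})

test_that("polyline distance agrees with a dense-sampling oracle", {
  set.seed(5)
  coast <- coastline(c(0, 4000, 9000, 7000), c(0, 3000, 1000, 8000))
  pts <- tibble::tibble(x = runif(20, -2000, 12000), y = runif(20, -2000, 10000))
  # brute force: nearest of points sampled every ~0.5 m along each segment
  dense <- purrr::map_dfr(seq_len(nrow(coast) - 1), function(i) {
    len <- sqrt(diff(coast$x[i + 0:1])^2 + diff(coast$y[i + 0:1])^2)
    t <- seq(0, 1, length.out = ceiling(len / 0.5) + 1)
    tibble::tibble(x = coast$x[i] + t * diff(coast$x[i + 0:1]),
                   y = coast$y[i] + t * diff(coast$y[i + 0:1]))
  })
  brute_km <- vapply(seq_len(nrow(pts)), function(j) {
    sqrt(min((dense$x - pts$x[j])^2 + (dense$y - pts$y[j])^2)) / 1000
  }, numeric(1))
  out <- distance_to_coast(pts, coast)
  expect_lt(max(abs(out$dist_km - brute_km)), 1e-3)  # within 1 m
})

test_that("coast distance is translation invariant", {
  set.seed(6)
  coast <- coastline(c(0, 4000, 9000), c(0, 5000, 2000))
  pts <- tibble::tibble(x = runif(30, 0, 10000), y = runif(30, 0, 10000))
  d0 <- distance_to_coast(pts, coast)$dist_km
  shift <- c(12345.6, -9876.5)
  coast2 <- coastline(coast$x + shift[1], coast$y + shift[2])
  pts2 <- dplyr::mutate(pts, x = x + shift[1], y = y + shift[2])
  expect_equal(distance_to_coast(pts2, coast2)$dist_km, d0, tolerance = 1e-9)
})

test_that("CRS mismatch between points and coastline is rejected", {
  coast <- coastline(c(0, 0), c(0, 1000), crs = "EPSG:32651")
  pts <- tibble::tibble(x = 1, y = 1)
  expect_error(distance_to_coast(pts, coast, crs = "EPSG:4326"), "CRS")
  expect_silent(distance_to_coast(pts, coast, crs = "EPSG:32651"))
})

test_that("coastline-distance zones split at 10 km (inclusive) and 25 km (inclusive)", {
  expect_equal(as.character(assign_zone(c(5, 15, 30, 10, 25, 0, 10.0001))),
               c("offshore", "middle", "inland", "offshore", "middle",
                 "offshore", "middle"))
  expect_error(assign_zone(-1), "nonnegative")
  d <- assign_zone(tibble::tibble(dist_km = c(3, 40)))
  expect_equal(as.character(d$coast_zone), c("offshore", "inland"))
})

test_that("fishnet means equal brute-force per-cell averages", {
  set.seed(31)
  px <- pixel_grid(24, 24, cell = 100,
                   fvc = runif(24 * 24), lst_k = rnorm(24 * 24, 300, 2))
  px$fvc[sample(nrow(px), 40)] <- NA
  coast <- straight_coast(-5000)
  net <- build_fishnet(px, coast, cell_length = 300, cell_size = 100,
                       min_valid_frac = 0.5)
  # independent aggregation: explicit pixel lists per 3x3 block
  px2 <- dplyr::mutate(px, ix = floor((x - 50) / 300), iy = floor((y - 50) / 300),
                       ok = !is.na(fvc) & !is.na(lst_k))
  for (k in seq_len(nrow(net))) {
    ix <- round((net$x[k] - 50) / 300 - 0.5)
    iy <- round((net$y[k] - 50) / 300 - 0.5)
    blk <- px2[px2$ix == ix & px2$iy == iy & px2$ok, ]
    expect_equal(net$mean_fvc[k], mean(blk$fvc), tolerance = 1e-12)
    expect_equal(net$mean_lst_k[k], mean(blk$lst_k), tolerance = 1e-12)
    expect_equal(net$n_valid[k], nrow(blk))
  }
  expect_true(all(net$n_valid >= 0.5 * 9))
})

test_that("uniform fields give uniform fishnet cells; empty cells are dropped", {
  px <- pixel_grid(12, 12, cell = 100, fvc = 0.5, lst_k = 300)
  blk <- px$row <= 3 & px$col <= 3
  px$fvc[blk] <- NA  # one fully invalid 300 m cell
  net <- build_fishnet(px, straight_coast(-1000), cell_length = 300,
                       cell_size = 100)
  expect_equal(nrow(net), 15)
  expect_true(all(net$mean_fvc == 0.5))
  expect_true(all(net$mean_lst_k == 300))
  px$fvc <- NA_real_
  expect_error(build_fishnet(px, straight_coast(-1000), cell_length = 300,
                             cell_size = 100), "no fishnet cell")
})

test_that("zone assignment partitions the retained fishnet cells", {
  sc <- generate_scene(tiny_spec(seed = 14))
  px <- recover_scene(sc)
  net <- build_fishnet(px, sc$coastline, cell_length = 900, cell_size = 300)
  expect_false(any(is.na(net$coast_zone)))
  expect_equal(sum(table(net$coast_zone)), nrow(net))
})

test_that("an exact linear LST-FVC relation is fitted exactly", {
  set.seed(17)
  net <- tibble::tibble(
    mean_fvc = runif(50),
    coast_zone = "offshore"
  ) |> dplyr::mutate(mean_lst_k = 310 - 5 * mean_fvc)
  fit <- fit_zone_regression(net, "offshore")
  td <- suppressWarnings(tidy(fit))  # summary.lm warns on a perfect fit
  expect_equal(td$slope, -5, tolerance = 1e-9)
  expect_equal(td$intercept, 310, tolerance = 1e-9)
  expect_equal(td$r_squared, 1, tolerance = 1e-9)
  expect_equal(td$n, 50L)
})

test_that("degenerate regressions are refused", {
  net <- tibble::tibble(mean_fvc = c(0.2, 0.4), mean_lst_k = c(300, 299),
                        coast_zone = "inland")
  expect_error(fit_zone_regression(net, "inland"), "fewer than 3")
  net <- tibble::tibble(mean_fvc = rep(0.3, 10), mean_lst_k = rnorm(10, 300),
                        coast_zone = "middle")
  expect_error(fit_zone_regression(net, "middle"), "degenerate")
})

test_that("construction slopes are recovered within sampling error", {
  sc <- generate_scene(landscape_spec(seed = 23))
  px <- recover_scene(sc)
  net <- build_fishnet(px, sc$coastline, cell_length = 900, cell_size = 300)
  td <- tidy(fit_zone_regression(net))
  truth <- sc$spec$lst_slopes[as.character(td$zone)]
  expect_true(all(abs(td$slope - truth) <= 3 * td$slope_se))
  # the paper's summer ordering: steeper cooling inland than offshore
  expect_lt(td$slope[td$zone == "inland"], td$slope[td$zone == "offshore"])
})
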