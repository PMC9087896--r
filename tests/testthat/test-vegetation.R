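test_that("NDVI follows the band-ratio definition, with NoData for degenerate pairs", {
  d <- tibble::tibble(
    red = c(0.5, 0.2, 0.0, NA, 0.1),
    nir = c(0.5, 0.6, 0.0, 0.3, NA)
  )
  out <- compute_ndvi(d)
  expect_equal(out$ndvi, c(0, 0.5, NA, NA, NA))
  expect_error(compute_ndvi(tibble::tibble(red = 0.1)), "NIR")
})

test_that("NDVI is invariant when both bands are scaled by a common factor", {
  set.seed(11)
  d <- tibble::tibble(red = runif(200, 0.01, 0.3), nir = runif(200, 0.01, 0.9))
  for (k in c(0.37, 2.7, 10)) {
    scaled <- dplyr::mutate(d, red = red * k, nir = nir * k)
    expect_equal(compute_ndvi(scaled)$ndvi, compute_ndvi(d)$ndvi,
                 tolerance = 1e-12)
  }
})

test_that("endpoint selection takes the NDVI quantiles and rejects degenerate grids", {
  # brute force on the enumerated list 0.00, 0.01, ..., 1.00: with linear
  # interpolation h = (n-1)p + 1 lands exactly on elements 6 and 96
  d <- tibble::tibble(ndvi = seq(0, 1, by = 0.01))
  ep <- select_endpoints(d, 5, 95)
  expect_equal(ep$soil, 0.05)
  expect_equal(ep$veg, 0.95)
  expect_error(select_endpoints(tibble::tibble(ndvi = rep(0.3, 50)), 5, 95),
               "degenerate")
  expect_error(select_endpoints(tibble::tibble(ndvi = NA_real_)), "finite")
  expect_error(select_endpoints(d, 95, 5))
})

test_that("fixed endpoints echo the configured soil/vegetation constants", {
  ep <- dimidiate_endpoints(0.06, 0.6)
  expect_equal(ep$soil, 0.06)
  expect_equal(ep$veg, 0.6)
  expect_error(dimidiate_endpoints(0.6, 0.6), "strictly less")
})

test_that("endpoints from NDVI/FVC extremes match direct substitution", {
  # symbolic limits fvc_min = 0, fvc_max = 1
  ep <- endpoints_from_extremes(0.1, 0.7, 0, 1)
  expect_equal(ep$soil, 0.1 - 0.7)
  expect_equal(ep$veg, 0.7)
  # frozen numeric oracle: independent substitution with
  # ndvi_min = 0, ndvi_max = 0.8, fvc_min = 0.05, fvc_max = 0.95:
  # soil = (0.95*0 - 0.95*0.8)/0.9, veg = (0.95*0.8 - 0.05*0)/0.9
  ep <- endpoints_from_extremes(0, 0.8, 0.05, 0.95)
  expect_equal(ep$soil, -0.8444444444444444, tolerance = 1e-12)
  expect_equal(ep$veg, 0.8444444444444444, tolerance = 1e-12)
  expect_error(endpoints_from_extremes(0, 0.8, 0.5, 0.5), "differ")
})

test_that("FVC inversion is linear between the endpoints and clamped outside", {
  ep <- dimidiate_endpoints(0.06, 0.6)
  d <- tibble::tibble(ndvi = c(0.06, 0.33, 0.9, 0.0, NA))
  out <- compute_fvc(d, ep)
  expect_equal(out$fvc, c(0, 0.5, 1, 0, NA))
  expect_error(compute_fvc(d, list(soil = 0.5, veg = 0.6)), "endpoints")
})

test_that("FVC is monotone nondecreasing in NDVI for fixed endpoints", {
  set.seed(7)
  for (i in 1:5) {
    nd <- sort(runif(100, -1, 1))
    fvc <- compute_fvc(tibble::tibble(ndvi = nd), dimidiate_endpoints())$fvc
    expect_true(all(diff(fvc) >= 0))
    expect_true(all(fvc >= 0 & fvc <= 1))
  }
})

test_that("FVC classes use lower-inclusive bins with a closed top bin", {
  d <- tibble::tibble(fvc = c(0.1, 0.5, 0.85, 0.2, 1.0, 0, 0.7999999, NA))
  out <- classify_fvc(d)
  expect_equal(as.character(out$fvc_class),
               c("BL&W", "SL-FVC", "H-FVC", "L-FVC", "H-FVC", "BL&W",
                 "M-FVC", NA))
  expect_error(classify_fvc(tibble::tibble(fvc = 1.2)), "\\[0, 1\\]")
})

test_that("classification partitions every finite pixel and areas sum to the total", {
  set.seed(3)
  d <- tibble::tibble(fvc = c(runif(500), rep(NA, 17)))
  out <- classify_fvc(d)
  expect_equal(sum(!is.na(out$fvc_class)), 500)
  tab <- class_area_table(out, fvc_class, cell_area_km2 = 0.09)
  expect_equal(sum(tab$area_km2), 500 * 0.09, tolerance = 1e-6)
  expect_equal(sum(tab$proportion_pct), 100, tolerance = 0.01)
  expect_equal(nrow(tab), 5)  # all five classes reported, zeros included
})

test_that("class areas scale with pixel count and cell area", {
  d <- tibble::tibble(fvc_class = factor(rep("M-FVC", 10),
                                         levels = fvc_class_levels()))
  tab <- class_area_table(d, fvc_class, 0.25)
  expect_equal(tab$area_km2[tab$class == "M-FVC"], 2.5)
  expect_equal(tab$proportion_pct[tab$class == "M-FVC"], 100)
  expect_error(class_area_table(d, fvc_class, 0), "positive")
  expect_error(
    class_area_table(tibble::tibble(fvc_class = factor(NA)), fvc_class, 1),
    "NoData")
})

test_that("published-style area rows reproduce their printed proportions", {
  areas <- tibble::tibble(
    class = fvc_class_levels(),
    area_km2 = c(540.87, 998.00, 1394.44, 1344.36, 1908.04)
  )
  pr <- class_proportions(areas)
  expect_equal(pr$proportion_pct[pr$class == "H-FVC"], 30.85)
  areas$area_km2 <- c(366.27, 1130.73, 1872.23, 1178.33, 1443.78)
  pr <- class_proportions(areas)
  expect_equal(pr$proportion_pct[pr$class == "H-FVC"], 24.10)
})

test_that("the vegetation chain recovers the generator's true FVC", {
  sc <- generate_scene(tiny_spec(seed = 9))
  px <- sc |> compute_ndvi() |> compute_fvc(sc$endpoints)
  land <- !sc$pixels$water
  expect_lt(max(abs(px$fvc[land] - sc$truth$fvc[land])), 1e-9)
  expect_true(all(is.na(px$fvc[!land])))
})
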