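test_that("DN calibration is the sensor's linear map and propagates NoData", {
  sensor <- sensor_profile("custom", gain = 0.05, offset = 1.2, k1 = 600, k2 = 1260)
  d <- tibble::tibble(thermal = c(100, 0, NA))
  out <- calibrate_dn(d, sensor)
  expect_equal(out$radiance, c(6.2, 1.2, NA))
})

test_that("quantized DN round-trips the forward radiance to one DN step", {
  sc <- generate_scene(tiny_spec(seed = 4), quantize = TRUE)
  # rebuild the forward at-sensor radiance from the truth
  b <- temperature_to_radiance(sc$truth$lst_k, sc$sensor)
  l_fwd <- (sc$truth$emissivity * b +
              (1 - sc$truth$emissivity) * sc$atm$l_down) * sc$atm$tau +
    sc$atm$l_up
  l_rec <- calibrate_dn(sc$pixels, sc$sensor)$radiance
  land <- !sc$pixels$water
  expect_lte(max(abs(l_rec[land] - l_fwd[land])), sc$sensor$gain)
})

test_that("surface radiance inverts the radiative transfer equation", {
  # transparent atmosphere over a black surface: B equals the sensor radiance
  atm0 <- atmosphere(tau = 1, l_up = 0, l_down = 0)
  d <- tibble::tibble(radiance = c(5, 8.5))
  expect_equal(solve_surface_radiance(d, 1, atm0)$surface_radiance, c(5, 8.5))
  # frozen substitution oracle: ((8 - 1)/0.8 - 0.05*1.6)/0.95
  atm <- atmosphere(tau = 0.8, l_up = 1.0, l_down = 1.6)
  out <- solve_surface_radiance(tibble::tibble(radiance = 8), 0.95, atm)
  expect_equal(out$surface_radiance, 9.126315789473684, tolerance = 1e-12)
  # sensor radiance equal to the upwelling path radiance -> nonpositive -> NA
  out <- solve_surface_radiance(tibble::tibble(radiance = 1.0), 0.95,
                                atmosphere(tau = 0.8, l_up = 1.0, l_down = 0))
  expect_true(is.na(out$surface_radiance))
  expect_error(atmosphere(tau = 0), "tau")
  expect_error(solve_surface_radiance(d, 0, atm0), "positive")
})

test_that("the inverse Planck relation hits K2 at B = K1/(e - 1) and is monotone", {
  sensor <- sensor_profile()
  expect_equal(radiance_to_temperature(sensor$k1 / (exp(1) - 1), sensor),
               sensor$k2, tolerance = 1e-9)
  b <- sort(runif(100, 0.1, 30))
  t <- radiance_to_temperature(b, sensor)
  expect_true(all(diff(t) > 0))
  expect_true(is.na(radiance_to_temperature(-1, sensor)))
  expect_true(is.na(radiance_to_temperature(0, sensor)))
})

test_that("temperature -> radiance -> temperature round-trips across 220-340 K", {
  for (id in c("tm_like", "etm_like", "oli_tirs_like")) {
    sensor <- sensor_profile(id)
    t0 <- seq(220, 340, by = 0.5)
    t1 <- radiance_to_temperature(temperature_to_radiance(t0, sensor), sensor)
    expect_lt(max(abs(t1 - t0)), 1e-9)
  }
})

test_that("the full thermal chain recovers the generator's true LST", {
  for (units in c("dn", "radiance")) {
    sc <- generate_scene(tiny_spec(seed = 12), thermal_as = units)
    px <- recover_scene(sc)
    land <- !sc$pixels$water
    expect_lt(max(abs(px$lst_k[land] - sc$truth$lst_k[land])), 1e-6)
  }
  expect_error(retrieve_lst(tibble::tibble(red = 1), sensor_profile(),
                            atmosphere()), "thermal")
})

test_that("with a transparent atmosphere and unit emissivity LST reduces to brightness temperature", {
  sc <- generate_scene(tiny_spec(seed = 2), thermal_as = "radiance")
  atm0 <- atmosphere(tau = 1, l_up = 0, l_down = 0)
  px <- retrieve_lst(sc$pixels, sc$sensor, atm0, emissivity = 1,
                     bounds = c(100, 500))
  bt <- radiance_to_temperature(sc$pixels$thermal, sc$sensor)
  expect_equal(px$lst_k, bt, tolerance = 1e-12)
})

test_that("surface radiance is strictly increasing in sensor radiance", {
  atm <- atmosphere(0.8, 1.0, 1.6)
  l <- sort(runif(50, 2, 12))
  b <- solve_surface_radiance(tibble::tibble(radiance = l), 0.97, atm)$surface_radiance
  expect_true(all(diff(b) > 0))
})

test_that("station validation reports MAE and RMSE over matched stations", {
  px <- pixel_grid(4, 4, lst_k = 300)
  st <- tibble::tibble(x = px$x[1:4], y = px$y[1:4],
                       temperature_k = c(300, 300, 300, 300))
  out <- validate_lst(px, st)
  expect_equal(out$mae_k, 0)
  expect_equal(out$rmse_k, 0)
  expect_equal(out$n, 4L)
  st$temperature_k <- 300 - c(1, -1, 1, -1)
  out <- validate_lst(px, st)
  expect_equal(out$mae_k, 1)
  expect_equal(out$rmse_k, 1)
  st2 <- st[1:2, ]
  st2$temperature_k <- 300 - c(3, 4)
  out <- validate_lst(px, st2)
  expect_equal(out$mae_k, 3.5)
  expect_equal(out$rmse_k, sqrt(12.5))
  px$lst_k <- NA_real_
  expect_error(validate_lst(px, st), "no station")
})

test_that("a transmissivity error degrades station MAE on noise-free stations", {
  sc <- generate_scene(tiny_spec(seed = 21))
  st <- generate_stations(sc, n = 20, noise_sd = 0, seed = 5)
  base <- sc |> compute_ndvi() |> compute_fvc(sc$endpoints)
  mae_for <- function(tau) {
    atm <- atmosphere(tau, sc$atm$l_up, sc$atm$l_down)
    validate_lst(retrieve_lst(base, sc$sensor, atm), st)$mae_k
  }
  mae_true <- mae_for(sc$atm$tau)
  expect_lt(mae_true, 1e-6)
  expect_gt(mae_for(sc$atm$tau - 0.1), mae_true)
  expect_gt(mae_for(min(1, sc$atm$tau + 0.1)), mae_true)
})
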