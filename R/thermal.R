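#' Thermal sensor profile
#'
#' Calibration for the thermal band: the linear DN-to-radiance map
#' (`gain`, `offset`) and the two Planck calibration constants `k1`
#' (W·m⁻²·sr⁻¹·μm⁻¹) and `k2` (kelvin) used by the inverse Planck relation.
#' Three named profiles ship with the package, carrying the published
#' thermal constants of the corresponding Landsat sensor families:
#' `"tm_like"` (K1 = 607.76, K2 = 1260.56), `"etm_like"` (K1 = 666.09,
#' K2 = 1282.71) and `"oli_tirs_like"` (K1 = 774.8853, K2 = 1321.0789).
#'
#' @param id One of the named profiles above, or any label when the four
#'   constants are supplied explicitly.
#' @param gain,offset Radiance per DN and radiance offset; `gain` must be
#'   positive.
#' @param k1,k2 Planck calibration constants; both positive.
#' @return An object of class `sensor_profile`.
#' @export
sensor_profile <- function(id = "oli_tirs_like", gain = NULL, offset = NULL,
                           k1 = NULL, k2 = NULL) {
  presets <- list(
    tm_like = list(gain = 0.055376, offset = 1.18, k1 = 607.76, k2 = 1260.56),
    etm_like = list(gain = 0.067087, offset = -0.07, k1 = 666.09, k2 = 1282.71),
    oli_tirs_like = list(gain = 3.342e-4, offset = 0.1,
                         k1 = 774.8853, k2 = 1321.0789)
  )
  base <- presets[[id]] %||% list()
  p <- list(id = id,
            gain = gain %||% base$gain, offset = offset %||% base$offset,
            k1 = k1 %||% base$k1, k2 = k2 %||% base$k2)
  if (any(vapply(p[c("gain", "offset", "k1", "k2")], is.null, logical(1)))) {
    abort("unknown profile id: supply gain, offset, k1 and k2 explicitly")
  }
  if (p$gain <= 0 || p$k1 <= 0 || p$k2 <= 0) {
    abort("gain, k1 and k2 must all be positive")
  }
  structure(p, class = "sensor_profile")
}

#' @export
print.sensor_profile <- function(x, ...) {
  cat(sprintf("Sensor profile '%s': gain %g, offset %g, K1 %g, K2 %g\n",
              x$id, x$gain, x$offset, x$k1, x$k2))
  invisible(x)
}

#' Per-scene atmospheric parameters
#'
#' The three quantities the thermal radiative transfer equation needs:
#' atmospheric transmissivity `tau` in the thermal band, and the upwelling
#' (`l_up`) and downwelling (`l_down`) longwave atmospheric radiances
#' (W·m⁻²·sr⁻¹·μm⁻¹). These come from an atmospheric-correction calculator
#' for the acquisition; they are configuration, not estimated here.
#'
#' @param tau Transmissivity in (0, 1].
#' @param l_up,l_down Nonnegative path radiances.
#' @return An object of class `atmosphere`.
#' @export
atmosphere <- function(tau = 0.85, l_up = 1.2, l_down = 2.0) {
  if (!is.numeric(tau) || tau <= 0 || tau > 1) abort("tau must be in (0, 1]")
  if (l_up < 0 || l_down < 0) abort("l_up and l_down must be nonnegative")
  structure(list(tau = tau, l_up = l_up, l_down = l_down), class = "atmosphere")
}

#' Convert thermal digital numbers to at-sensor radiance
#'
#' Applies the sensor's absolute calibration `L = gain * DN + offset` per
#' pixel. `NA` propagates.
#'
#' @param data Pixel data frame with the thermal DN column.
#' @param sensor A [sensor_profile()].
#' @param dn Unquoted DN column name (default `thermal`).
#' @return `data` with an added `radiance` column.
#' @export
calibrate_dn <- function(data, sensor, dn = thermal) {
  data <- as_pixel_df(data)
  stopifnot(inherits(sensor, "sensor_profile"))
  v <- eval_tidy(enquo(dn), data)
  if (is.null(v)) abort("thermal DN column not found")
  dplyr::mutate(as_tibble(data), radiance = sensor$gain * v + sensor$offset)
}

#' Solve the radiative transfer equation for surface blackbody radiance
#'
#' Inverts \eqn{L_{sen} = (\epsilon B(T_s) + (1-\epsilon) L_d)\tau + L_u}
#' for the surface blackbody radiance:
#' \deqn{B(T_s) = \frac{(L_{sen} - L_u)/\tau - (1-\epsilon) L_d}{\epsilon}}
#' Pixels with a nonpositive result (sensor radiance at or below the
#' atmospheric path radiance) become `NA`.
#'
#' @param data Pixel data frame with an at-sensor radiance column.
#' @param emissivity Surface emissivity: a single number in (0, 1], a
#'   numeric vector of pixel emissivities, or the name of a column in
#'   `data` (as a string).
#' @param atm An [atmosphere()] object.
#' @param radiance Unquoted at-sensor radiance column name.
#' @return `data` with an added `surface_radiance` column.
#' @export
solve_surface_radiance <- function(data, emissivity, atm, radiance = radiance) {
  data <- as_pixel_df(data)
  stopifnot(inherits(atm, "atmosphere"))
  l <- eval_tidy(enquo(radiance), data)
  eps <- resolve_emissivity(data, emissivity)
  if (any(eps <= 0, na.rm = TRUE)) abort("emissivity must be positive")
  if (any(eps > 1, na.rm = TRUE)) abort("emissivity cannot exceed 1")
  b <- ((l - atm$l_up) / atm$tau - (1 - eps) * atm$l_down) / eps
  b[!is.na(b) & b <= 0] <- NA_real_
  dplyr::mutate(as_tibble(data), surface_radiance = b)
}

resolve_emissivity <- function(data, emissivity) {
  if (is.character(emissivity) && length(emissivity) == 1 &&
      emissivity %in% names(data)) {
    return(data[[emissivity]])
  }
  if (is.numeric(emissivity)) {
    if (length(emissivity) %in% c(1L, nrow(data))) return(emissivity)
    abort("numeric emissivity must be a scalar or one value per pixel")
  }
  abort("emissivity must be numeric or the name of a column in `data`")
}

#' Emissivity from fractional vegetation cover
#'
#' Minimal two-endmember emissivity scheme: pixels at or above the FVC
#' threshold take the vegetation emissivity, the rest (including `NA` FVC,
#' treated as non-vegetated) the soil/urban value. The published analysis
#' does not state its emissivity source; this scheme is the package's
#' documented gap-fill, driven by the FVC field the pipeline already
#' computes.
#'
#' @param fvc Numeric FVC vector in \eqn{[0, 1]}.
#' @param e_veg,e_soil Endmember emissivities (defaults 0.986 and 0.964).
#' @param threshold FVC at or above which a pixel counts as vegetated
#'   (default 0.5).
#' @return Numeric emissivity vector.
#' @export
emissivity_from_fvc <- function(fvc, e_veg = 0.986, e_soil = 0.964,
                                threshold = 0.5) {
  ifelse(!is.na(fvc) & fvc >= threshold, e_veg, e_soil)
}

#' Inverse Planck conversion: blackbody radiance to temperature
#'
#' Converts surface blackbody radiance to kelvin with
#' \eqn{T = K_2 / \ln(K_1/B + 1)}. Strictly increasing in `B`; nonpositive
#' radiance yields `NA` rather than an error. Given a data frame, adds an
#' `lst_k` column from its `surface_radiance` column; given a numeric
#' vector, returns temperatures directly.
#'
#' @param x Numeric radiance vector, or a pixel data frame with a
#'   `surface_radiance` column.
#' @param sensor A [sensor_profile()] providing `k1` and `k2`.
#' @param ... Passed between methods.
#' @return Temperatures in kelvin (vector), or `x` with an `lst_k` column.
#' @seealso [temperature_to_radiance()] for the closed-form inverse.
#' @export
radiance_to_temperature <- function(x, sensor, ...) {
  UseMethod("radiance_to_temperature")
}

#' @export
radiance_to_temperature.numeric <- function(x, sensor, ...) {
  stopifnot(inherits(sensor, "sensor_profile"))
  t <- ifelse(!is.na(x) & x > 0, sensor$k2 / log(sensor$k1 / x + 1), NA_real_)
  t
}

#' @export
radiance_to_temperature.data.frame <- function(x, sensor, ...) {
  check_columns(x, "surface_radiance", "pixel table")
  dplyr::mutate(as_tibble(x),
                lst_k = radiance_to_temperature(.data$surface_radiance, sensor))
}

#' Planck radiance of a blackbody at temperature T
#'
#' The band-effective Planck function \eqn{B = K_1 / (e^{K_2/T} - 1)},
#' the exact inverse of [radiance_to_temperature()].
#'
#' @param t_k Temperature in kelvin (positive).
#' @param sensor A [sensor_profile()].
#' @return Radiance in the sensor's thermal band units.
#' @export
temperature_to_radiance <- function(t_k, sensor) {
  stopifnot(inherits(sensor, "sensor_profile"))
  ifelse(!is.na(t_k) & t_k > 0, sensor$k1 / (exp(sensor$k2 / t_k) - 1), NA_real_)
}

#' Retrieve land surface temperature from a scene
#'
#' Runs the full thermal chain: DN-to-radiance calibration (skipped when
#' the thermal band already holds radiance), radiative-transfer inversion
#' for surface blackbody radiance, and the inverse Planck conversion to
#' kelvin. Retrieved temperatures outside the plausibility bounds are
#' masked to `NA` rather than raising an error, so batch runs survive
#' degenerate pixels.
#'
#' @param data Pixel data frame (or scene) with a `thermal` column; when
#'   `emissivity = "auto"` it must also carry an `fvc` column.
#' @param sensor A [sensor_profile()].
#' @param atm An [atmosphere()] object.
#' @param emissivity `"auto"` for the FVC-threshold scheme
#'   ([emissivity_from_fvc()]), a constant in (0, 1], a per-pixel numeric
#'   vector, or a column name.
#' @param thermal_units `"dn"` or `"radiance"`; defaults to the
#'   `thermal_units` attribute of `data` when present, else `"dn"`.
#' @param bounds Plausibility bounds in kelvin (default `c(220, 340)`).
#' @return `data` with added `radiance`, `surface_radiance` and `lst_k`
#'   columns.
#' @export
retrieve_lst <- function(data, sensor, atm, emissivity = "auto",
                         thermal_units = NULL, bounds = c(220, 340)) {
  units_attr <- attr(as_pixel_df(data), "thermal_units", exact = TRUE)
  data <- as_pixel_df(data)
  check_columns(data, "thermal", "scene")
  thermal_units <- thermal_units %||% units_attr %||% "dn"
  thermal_units <- match.arg(thermal_units, c("dn", "radiance"))
  if (identical(emissivity, "auto")) {
    check_columns(data, "fvc", "scene (emissivity = \"auto\")")
    emissivity <- emissivity_from_fvc(data$fvc)
  }
  out <- if (thermal_units == "dn") {
    calibrate_dn(data, sensor)
  } else {
    dplyr::mutate(as_tibble(data), radiance = .data$thermal)
  }
  out <- solve_surface_radiance(out, emissivity, atm)
  out <- radiance_to_temperature(out, sensor)
  bad <- !is.na(out$lst_k) & (out$lst_k < bounds[1] | out$lst_k > bounds[2])
  out$lst_k[bad] <- NA_real_
  attr(out, "thermal_units") <- thermal_units
  out
}

#' Validate retrieved LST against station records
#'
#' Matches each station to the pixel whose center is nearest its location
#' (point sampling), drops stations landing on `NA` pixels, and reports the
#' mean absolute error, root-mean-square error and matched count of
#' predicted minus observed temperature.
#'
#' @param data Pixel data frame with `x`, `y` and `lst_k` columns.
#' @param stations Data frame with `x`, `y` and `temperature_k` columns
#'   (as from [generate_stations()]).
#' @return A one-row tibble with `mae_k`, `rmse_k` and `n`, plus a
#'   `residuals` attribute holding the per-station table.
#' @export
validate_lst <- function(data, stations) {
  data <- as_pixel_df(data)
  check_columns(data, c("x", "y", "lst_k"), "LST table")
  check_columns(stations, c("x", "y", "temperature_k"), "station table")
  pred <- vapply(seq_len(nrow(stations)), function(i) {
    d2 <- (data$x - stations$x[i])^2 + (data$y - stations$y[i])^2
    data$lst_k[which.min(d2)]
  }, numeric(1))
  res <- dplyr::mutate(as_tibble(stations), predicted_k = pred,
                       residual_k = pred - .data$temperature_k)
  matched <- dplyr::filter(res, !is.na(.data$predicted_k))
  if (nrow(matched) == 0) abort("no station falls on a valid LST pixel")
  out <- tibble(
    mae_k = mean(abs(matched$residual_k)),
    rmse_k = sqrt(mean(matched$residual_k^2)),
    n = nrow(matched)
  )
  attr(out, "residuals") <- matched
  out
}
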