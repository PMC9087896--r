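#' Landscape specification for a synthetic coastal scene
#'
#' Describes the simulated study area: a coastal strip (sea to the west of
#' a piecewise-linear coastline) backed by vegetated coastal mountains, an
#' urban belt, inland agriculture and scattered bare ground. Land-cover
#' fractions apply to the land pixels; water is whatever lies seaward of
#' the coastline. The default 300 m cells on a 96×128 grid span roughly
#' 38 km inland, so all three coastline-distance zones are populated.
#'
#' @param rows,cols Grid dimensions (each ≥ 16).
#' @param cell_size Pixel size in meters (> 0); default 300.
#' @param coast Optional [coastline()] geometry; by default a gently
#'   curving shoreline a few kilometers from the western edge.
#' @param cover Named nonnegative fractions for `forest`, `urban`,
#'   `agriculture`, `bare`, summing to 1 over land.
#' @param cover_fvc Named list of length-2 FVC ranges per cover class
#'   (summer values); defaults: forest 0.82–0.98, urban 0.02–0.20,
#'   agriculture 0.50–0.80, bare 0.00–0.12.
#' @param deciduous_frac Fraction of the forest canopy that is deciduous in
#'   \eqn{[0, 1]} (default 0.5); deciduous foliage (and crops) is lost in
#'   winter, lowering winter FVC.
#' @param season `"summer"` or `"winter"`.
#' @param lst_intercepts,lst_slopes Named per-zone (`offshore`, `middle`,
#'   `inland`) intercepts (kelvin at FVC 0) and slopes (kelvin per unit
#'   FVC) of the true LST field; defaults are seasonal: summer
#'   (303, 304, 305.5) K with slopes (−3, −4.5, −6), winter
#'   (277, 277.5, 278) K with zero slopes.
#' @param lst_noise_sd Pixel LST noise sd in kelvin (default 0.5).
#' @param blur_km Spatial blending (km) of the cover-class bands
#'   (default 3).
#' @param seed Integer random seed; the same spec and seed give
#'   bit-identical scenes.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(rows = 96, cols = 128, cell_size = 300,
                           coast = NULL,
                           cover = c(forest = 0.25, urban = 0.25,
                                     agriculture = 0.35, bare = 0.15),
                           cover_fvc = NULL,
                           deciduous_frac = 0.5,
                           season = c("summer", "winter"),
                           lst_intercepts = NULL, lst_slopes = NULL,
                           lst_noise_sd = 0.5, blur_km = 3, seed = 1L) {
  season <- match.arg(season)
  if (rows < 16 || cols < 16) abort("rows and cols must both be at least 16")
  if (cell_size <= 0) abort("cell_size must be positive")
  classes <- c("forest", "urban", "agriculture", "bare")
  cover <- cover[classes[classes %in% names(cover)]]
  full <- setNames(rep(0, length(classes)), classes)
  full[names(cover)] <- cover
  if (any(full < 0)) abort("cover fractions must be nonnegative")
  if (abs(sum(full) - 1) > 1e-9) abort("cover fractions must sum to 1")
  default_fvc <- list(forest = c(0.82, 0.98), urban = c(0.02, 0.20),
                      agriculture = c(0.50, 0.80), bare = c(0.00, 0.12))
  for (nm in names(cover_fvc)) default_fvc[[nm]] <- cover_fvc[[nm]]
  if (deciduous_frac < 0 || deciduous_frac > 1) {
    abort("deciduous_frac must lie in [0, 1]")
  }
  extent_y <- rows * cell_size
  coast <- coast %||% default_coastline(extent_y)
  check_columns(coast, c("x", "y"), "coastline")
  if (is.null(lst_intercepts)) {
    lst_intercepts <- if (season == "summer") {
      c(offshore = 303, middle = 304, inland = 305.5)
    } else {
      c(offshore = 277, middle = 277.5, inland = 278)
    }
  }
  if (is.null(lst_slopes)) {
    lst_slopes <- if (season == "summer") {
      c(offshore = -3, middle = -4.5, inland = -6)
    } else {
      c(offshore = 0, middle = 0, inland = 0)
    }
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size, coast = coast, cover = full,
                 cover_fvc = default_fvc, deciduous_frac = deciduous_frac,
                 season = season, lst_intercepts = lst_intercepts,
                 lst_slopes = lst_slopes, lst_noise_sd = lst_noise_sd,
                 blur_km = blur_km, seed = as.integer(seed)),
            class = "landscape_spec")
}

# a shoreline running roughly south-north a few km from the west edge,
# bowing inland mid-scene like an inner bay
default_coastline <- function(extent_y) {
  ys <- seq(-0.05, 1.05, length.out = 7) * extent_y
  xs <- c(2500, 3200, 5200, 6500, 5200, 3000, 2200)
  coastline(xs, ys)
}

# x-position of the coast at height y (linear interpolation between
# control points); water lies at x < coast_x(y)
coast_x_at <- function(coast, y) {
  o <- order(coast$y)
  stats::approx(coast$y[o], coast$x[o], xout = y, rule = 2)$y
}

#' Generate a synthetic coastal scene with known ground truth
#'
#' Builds a Landsat-like multiband scene by running the analysis chain
#' backwards from a manufactured truth: a true FVC field is laid out over
#' the landscape (coastal mountain forest, urban belt, inland agriculture,
#' bare patches), mapped to NDVI through the dimidiate endpoints and then
#' to a consistent red/NIR reflectance pair; a true LST field (linear in
#' FVC within each coastline-distance zone, plus noise) is pushed through
#' the Planck function and the radiative transfer equation to an at-sensor
#' thermal band. Because the forward model is the exact inverse of the
#' analysis chain, the pipeline recovers the truth to numerical precision
#' — which is what makes the recovery tests sharp. Pixels seaward of the
#' coastline are water: `NA` in every band.
#'
#' @param spec A [landscape_spec()].
#' @param sensor A [sensor_profile()].
#' @param atm An [atmosphere()] object.
#' @param endpoints Dimidiate endpoints used in the forward NDVI map
#'   (default the fixed 0.06/0.6 pair).
#' @param thermal_as Store the thermal band as unitless `"dn"` (inverse
#'   calibration applied; default) or as at-sensor `"radiance"`.
#' @param quantize When storing DN, round to integers and clamp to
#'   \eqn{[0, 65535]} (16-bit archive realism). Off by default: float DN
#'   keeps the forward chain exactly invertible, so LST round-trips to
#'   numerical precision; quantization limits recovery to about one DN
#'   step.
#' @param date Optional acquisition tag (e.g. `"2020.06"`).
#' @return An object of class `coastveg_scene`: a list with `pixels`
#'   (tibble: `row`, `col`, `x`, `y`, `water`, `dist_km`, `red`, `nir`,
#'   `thermal`), `truth` (tibble: `fvc`, `lst_k`, `emissivity`,
#'   `cover_class` per pixel), `coastline`, `endpoints`, `sensor`, `atm`,
#'   `spec`, `season`, `date`.
#' @export
generate_scene <- function(spec, sensor = sensor_profile(), atm = atmosphere(),
                           endpoints = dimidiate_endpoints(),
                           thermal_as = c("dn", "radiance"),
                           quantize = FALSE, date = NULL) {
  stopifnot(inherits(spec, "landscape_spec"),
            inherits(sensor, "sensor_profile"),
            inherits(atm, "atmosphere"))
  thermal_as <- match.arg(thermal_as)
  with_seed(spec$seed, {
    cs <- spec$cell_size
    grid <- tidyr::expand_grid(row = seq_len(spec$rows),
                               col = seq_len(spec$cols)) |>
      dplyr::mutate(x = (.data$col - 0.5) * cs, y = (.data$row - 0.5) * cs)
    grid$water <- grid$x < coast_x_at(spec$coast, grid$y)
    grid <- distance_to_coast(grid, spec$coast)
    n_land <- sum(!grid$water)
    if (n_land == 0) abort("the coastline leaves no land in the scene")

    # band the land into cover classes by blurred distance from the coast:
    # forest hugs the coastal mountains, then urban, then agriculture,
    # with bare ground scattered throughout
    land <- which(!grid$water)
    score <- grid$dist_km[land] + rnorm(n_land, 0, spec$blur_km)
    bare_draw <- runif(n_land)
    p_bare <- spec$cover[["bare"]]
    is_bare <- bare_draw < p_bare
    ranked <- rank(score, ties.method = "first")
    nonbare <- spec$cover[c("forest", "urban", "agriculture")]
    nonbare <- if (sum(nonbare) > 0) nonbare / sum(nonbare) else nonbare
    cuts <- cumsum(nonbare) * n_land
    band <- findInterval(ranked, cuts, left.open = TRUE) + 1L
    cover <- c("forest", "urban", "agriculture")[pmin(band, 3L)]
    cover[is_bare] <- "bare"
    grid$cover_class <- NA_character_
    grid$cover_class[land] <- cover

    # true FVC per pixel from the class ranges, with winter foliage loss
    fvc <- rep(NA_real_, nrow(grid))
    for (cl in names(spec$cover_fvc)) {
      idx <- which(!is.na(grid$cover_class) & grid$cover_class == cl)
      if (length(idx) == 0) next
      r <- spec$cover_fvc[[cl]]
      fvc[idx] <- runif(length(idx), r[1], r[2])
    }
    if (spec$season == "winter") {
      dec <- spec$deciduous_frac
      i_f <- which(grid$cover_class %in% "forest")
      fvc[i_f] <- fvc[i_f] * (1 - 0.65 * dec)
      i_a <- which(grid$cover_class %in% "agriculture")
      fvc[i_a] <- fvc[i_a] * 0.3
    }
    fvc <- clamp(fvc, 0, 1)

    # reflectances consistent with NDVI = soil + fvc * (veg - soil)
    ndvi <- endpoints$soil + fvc * (endpoints$veg - endpoints$soil)
    red <- runif(nrow(grid), 0.05, 0.22)
    # keep NIR physical for large endpoints; degenerate ndvi = 1 needs red = 0
    hi <- pmin(0.22, 0.95 * (1 - ndvi) / pmax(1 + ndvi, 1e-12))
    red <- pmin(red, hi)
    nir <- ifelse(!is.na(ndvi) & ndvi >= 1, 0.5,
                  red * (1 + ndvi) / (1 - ndvi))
    red[!is.na(ndvi) & ndvi >= 1] <- 0
    red[grid$water] <- NA_real_
    nir[grid$water] <- NA_real_

    # true LST: per-zone linear response to FVC plus pixel noise
    zone <- as.character(assign_zone(grid$dist_km))
    lst <- spec$lst_intercepts[zone] + spec$lst_slopes[zone] * fvc +
      rnorm(nrow(grid), 0, spec$lst_noise_sd)
    lst <- unname(lst)
    lst[grid$water] <- NA_real_

    # thermal band: Planck forward, radiative transfer forward, then the
    # sensor's inverse calibration
    emis <- emissivity_from_fvc(fvc)
    emis[grid$water] <- NA_real_
    b <- temperature_to_radiance(lst, sensor)
    l_sen <- (emis * b + (1 - emis) * atm$l_down) * atm$tau + atm$l_up
    thermal <- if (thermal_as == "dn") {
      dn <- (l_sen - sensor$offset) / sensor$gain
      if (quantize) clamp(round(dn), 0, 65535) else dn
    } else {
      l_sen
    }

    pixels <- grid |>
      dplyr::select("row", "col", "x", "y", "water", "dist_km") |>
      dplyr::mutate(red = red, nir = nir, thermal = thermal)
    attr(pixels, "thermal_units") <- thermal_as
    attr(pixels, "cell_size") <- cs
    truth <- grid |>
      dplyr::select("row", "col", "x", "y") |>
      dplyr::mutate(fvc = fvc, lst_k = lst, emissivity = emis,
                    cover_class = grid$cover_class)
    structure(list(pixels = pixels, truth = truth, coastline = spec$coast,
                   endpoints = endpoints, sensor = sensor, atm = atm,
                   spec = spec, season = spec$season, date = date,
                   scene_id = sprintf("synth-%s-%d", spec$season, spec$seed)),
              class = "coastveg_scene")
  })
}

#' @export
print.coastveg_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic coastal scene '%s': %d x %d pixels at %g m (%s), %d water px\n",
    x$scene_id, x$spec$rows, x$spec$cols, x$spec$cell_size, x$season,
    sum(x$pixels$water)))
  invisible(x)
}

#' Sample synthetic station records
#'
#' Draws `n` meteorological-station records from a scene's ground truth:
#' each station sits at a random land pixel center (point sampling) and
#' observes the true LST there plus Gaussian noise.
#'
#' @param scene A [generate_scene()] result (or its `truth` tibble with an
#'   `lst_k` column).
#' @param n Number of stations (≥ 1); default 15.
#' @param noise_sd Observation noise sd in kelvin (≥ 0); default 2.
#' @param seed Integer seed for the draw.
#' @return A tibble with `station_id`, `x`, `y`, `temperature_k`,
#'   `scene_id`.
#' @export
generate_stations <- function(scene, n = 15, noise_sd = 2, seed = 1L) {
  if (!is.numeric(n) || n < 1) abort("n must be at least 1")
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  truth <- if (inherits(scene, "coastveg_scene")) scene$truth else as_tibble(scene)
  check_columns(truth, c("x", "y", "lst_k"), "truth table")
  scene_id <- if (inherits(scene, "coastveg_scene")) scene$scene_id else "scene"
  land <- dplyr::filter(truth, !is.na(.data$lst_k))
  if (nrow(land) == 0) abort("no land pixels to place stations on")
  with_seed(seed, {
    idx <- sample.int(nrow(land), n, replace = n > nrow(land))
    tibble(
      station_id = sprintf("st%02d", seq_len(n)),
      x = land$x[idx], y = land$y[idx],
      temperature_k = land$lst_k[idx] + rnorm(n, 0, noise_sd),
      scene_id = scene_id
    )
  })
}
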