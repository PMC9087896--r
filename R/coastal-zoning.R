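#' Coastline polyline
#'
#' A piecewise-linear coastline in projected meters, ordered along the
#' shore. Distances and the land/water split are measured against this
#' geometry.
#'
#' @param x,y Numeric vertex coordinates (≥ 2 finite vertices).
#' @param crs Optional CRS identifier carried as an attribute.
#' @return A tibble of class `coastveg_coastline` with columns `x`, `y`.
#' @export
coastline <- function(x, y, crs = NULL) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("a coastline needs at least two (x, y) vertices")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("coastline vertices must be finite")
  }
  out <- tibble(x = as.numeric(x), y = as.numeric(y))
  attr(out, "crs") <- crs
  class(out) <- c("coastveg_coastline", class(out))
  out
}

# minimum Euclidean distance (meters) from points to a polyline
point_to_polyline_m <- function(px, py, coast) {
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(coast) - 1)) {
    x1 <- coast$x[i]; y1 <- coast$y[i]
    x2 <- coast$x[i + 1]; y2 <- coast$y[i + 1]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t <- if (len2 == 0) rep(0, length(px)) else
      clamp(((px - x1) * dx + (py - y1) * dy) / len2, 0, 1)
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Distance to the coastline
#'
#' Adds `dist_km`, the Euclidean distance in kilometers from each point
#' (pixel center or fishnet-cell center) to the nearest point of the
#' coastline polyline. Both inputs must share the same projected CRS.
#'
#' @param data Data frame with `x`, `y` coordinate columns (meters).
#' @param coast A [coastline()] object (or data frame of vertices).
#' @param crs Optional CRS identifier of `data`; when both it and the
#'   coastline carry a CRS they must match.
#' @return `data` with an added `dist_km` column.
#' @export
distance_to_coast <- function(data, coast, crs = NULL) {
  data <- as_pixel_df(data)
  check_columns(data, c("x", "y"), "point table")
  check_columns(coast, c("x", "y"), "coastline")
  coast_crs <- attr(coast, "crs", exact = TRUE)
  if (!is.null(crs) && !is.null(coast_crs) && !identical(crs, coast_crs)) {
    abort("CRS mismatch between points and coastline")
  }
  d <- point_to_polyline_m(data$x, data$y, coast) / 1000
  dplyr::mutate(as_tibble(data), dist_km = d)
}

#' Coastline-distance zones
#'
#' Assigns the three coastline-distance bands: offshore (≤ 10 km), middle
#' (10–25 km, upper bound inclusive) and inland (> 25 km). Given a data
#' frame, reads `dist_km` and adds a `coast_zone` factor column; given a
#' numeric distance vector, returns the factor directly.
#'
#' @param x Numeric distances in km, or a data frame with a `dist_km`
#'   column.
#' @param breaks Two increasing zone thresholds in km (default
#'   `c(10, 25)`).
#' @param ... Passed between methods.
#' @return A factor with levels `offshore`, `middle`, `inland`, or `x`
#'   with an added `coast_zone` column.
#' @export
assign_zone <- function(x, breaks = c(10, 25), ...) UseMethod("assign_zone")

#' @export
assign_zone.numeric <- function(x, breaks = c(10, 25), ...) {
  if (length(breaks) != 2 || breaks[1] >= breaks[2]) {
    abort("breaks must be two strictly increasing thresholds (km)")
  }
  if (any(x < 0, na.rm = TRUE)) abort("distances must be nonnegative")
  labels <- c("offshore", "middle", "inland")
  idx <- 1L + (x > breaks[1]) + (x > breaks[2])
  factor(labels[idx], levels = labels)
}

#' @export
assign_zone.data.frame <- function(x, breaks = c(10, 25), ...) {
  check_columns(x, "dist_km", "table")
  dplyr::mutate(as_tibble(x), coast_zone = assign_zone(.data$dist_km, breaks))
}

#' Aggregate FVC and LST on a fishnet grid
#'
#' Lays a regular square grid of side `cell_length` over the pixels
#' (snapped to the raster origin), averages FVC and LST over the valid
#' pixels of each cell, and labels each retained cell with its
#' coastline-distance zone measured from the cell center. A pixel is valid
#' when both its FVC and LST are non-`NA`; cells whose valid count falls
#' below `min_valid_frac` of the expected pixel count are dropped.
#'
#' @param data Pixel data frame with `x`, `y`, `fvc` and `lst_k` columns.
#' @param coast A [coastline()] object.
#' @param cell_length Fishnet cell side in meters (default 100); must be
#'   at least the raster cell size.
#' @param cell_size Raster pixel size in meters; inferred from the `x`
#'   spacing when omitted.
#' @param min_valid_frac Minimum valid fraction per retained cell
#'   (default 0.5).
#' @param breaks Zone thresholds in km passed to [assign_zone()].
#' @return A tibble with `cell_id`, cell-center `x`, `y`, `mean_fvc`,
#'   `mean_lst_k`, `n_valid`, `dist_km` and `coast_zone`.
#' @export
build_fishnet <- function(data, coast, cell_length = 100, cell_size = NULL,
                          min_valid_frac = 0.5, breaks = c(10, 25)) {
  data <- as_pixel_df(data)
  check_columns(data, c("x", "y", "fvc", "lst_k"), "pixel table")
  cell_size <- cell_size %||% attr(data, "cell_size", exact = TRUE) %||%
    infer_cell_size(data$x)
  if (!is.numeric(cell_length) || cell_length < cell_size) {
    abort("cell_length must be numeric and at least the raster cell size")
  }
  x0 <- min(data$x) - cell_size / 2
  y0 <- min(data$y) - cell_size / 2
  expected <- (cell_length / cell_size)^2
  cells <- data |>
    as_tibble() |>
    dplyr::mutate(
      ix = floor((.data$x - x0) / cell_length),
      iy = floor((.data$y - y0) / cell_length),
      valid = !is.na(.data$fvc) & !is.na(.data$lst_k)
    ) |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(
      mean_fvc = mean(.data$fvc[.data$valid]),
      mean_lst_k = mean(.data$lst_k[.data$valid]),
      n_valid = sum(.data$valid),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_valid >= min_valid_frac * expected,
                  .data$n_valid > 0) |>
    dplyr::mutate(
      x = x0 + (.data$ix + 0.5) * cell_length,
      y = y0 + (.data$iy + 0.5) * cell_length,
      cell_id = sprintf("c%04d_%04d", .data$ix, .data$iy)
    )
  if (nrow(cells) == 0) abort("no fishnet cell passed the valid-pixel filter")
  cells |>
    distance_to_coast(coast) |>
    assign_zone(breaks) |>
    dplyr::select("cell_id", "x", "y", "mean_fvc", "mean_lst_k",
                  "n_valid", "dist_km", "coast_zone")
}

infer_cell_size <- function(x) {
  ux <- sort(unique(x))
  if (length(ux) < 2) abort("cannot infer cell size: supply `cell_size`")
  min(diff(ux))
}

#' Per-zone linear fit of mean LST on mean FVC
#'
#' Ordinary least squares of fishnet-cell mean LST on mean FVC within each
#' coastline-distance zone. The slope (kelvin per unit FVC) measures the
#' cooling effect of vegetation in that zone; in the published summer
#' analyses it is negative everywhere and steepest inland.
#'
#' @param data A [build_fishnet()] table.
#' @param zone Optional single zone label to fit; default fits every zone
#'   present.
#' @return An object of class `coastveg_zone_fit`; use [tidy()] for the
#'   per-zone coefficient table, [glance()] for a one-row summary and
#'   [ggplot2::autoplot()] for the fitted scatter.
#' @export
fit_zone_regression <- function(data, zone = NULL) {
  check_columns(data, c("mean_fvc", "mean_lst_k", "coast_zone"), "fishnet table")
  zones <- if (is.null(zone)) {
    as.character(unique(data$coast_zone))
  } else {
    as.character(zone)
  }
  fits <- lapply(setNames(zones, zones), function(z) {
    d <- dplyr::filter(data, .data$coast_zone == z,
                       !is.na(.data$mean_fvc), !is.na(.data$mean_lst_k))
    if (nrow(d) < 3) {
      abort(sprintf("zone '%s' has fewer than 3 fishnet cells", z))
    }
    if (stats::var(d$mean_fvc) == 0) {
      abort(sprintf("degenerate fit: FVC is constant in zone '%s'", z))
    }
    lm(mean_lst_k ~ mean_fvc, data = d)
  })
  structure(list(fits = fits, data = as_tibble(data)),
            class = "coastveg_zone_fit")
}

#' @export
print.coastveg_zone_fit <- function(x, ...) {
  cat("Per-zone LST ~ FVC linear fits\n")
  print(generics::tidy(x), ...)
  invisible(x)
}
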