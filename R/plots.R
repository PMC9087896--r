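#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_line
#'   geom_smooth geom_col facet_wrap labs scale_fill_viridis_c
#'   scale_fill_brewer theme_minimal
#' @export
ggplot2::autoplot

#' Map a pixel column of a scene
#'
#' Quick-look raster map of any pixel column (default the true FVC) of a
#' synthetic scene; water renders as missing.
#'
#' @param object A [generate_scene()] result.
#' @param value Unquoted column of `object$truth` (or `object$pixels`) to
#'   map; default `fvc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coastveg_scene
#' @export
autoplot.coastveg_scene <- function(object, value = fvc, ...) {
  q <- enquo(value)
  src <- if (as_name(q) %in% names(object$truth)) object$truth else object$pixels
  ggplot(src, aes(x = .data$x / 1000, y = .data$y / 1000, fill = !!q)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey85") +
    labs(x = "easting (km)", y = "northing (km)",
         title = sprintf("Scene %s", object$scene_id)) +
    theme_minimal()
}

#' Plot per-zone LST ~ FVC fits
#'
#' Fishnet-cell scatter of mean LST against mean FVC, faceted by
#' coastline-distance zone, with the fitted OLS line.
#'
#' @param object A [fit_zone_regression()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coastveg_zone_fit
#' @export
autoplot.coastveg_zone_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$mean_fvc, y = .data$mean_lst_k)) +
    geom_point(alpha = 0.3, size = 0.6) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "firebrick", linewidth = 0.6) +
    facet_wrap(~coast_zone) +
    labs(x = "mean FVC", y = "mean LST (K)") +
    theme_minimal()
}

#' Plot the URI time trend by season
#'
#' @param object A [uri_trend()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coastveg_uri_trend
#' @export
autoplot.coastveg_uri_trend <- function(object, ...) {
  ggplot(object, aes(x = .data$year, y = .data$uri, colour = .data$season)) +
    geom_line() +
    geom_point() +
    labs(x = "year", y = "URI") +
    theme_minimal()
}

#' Stacked class-proportion bars across scenes
#'
#' @param areas A long class-area table with `date`, `class` and either
#'   `proportion_pct` or `area_km2`.
#' @return A ggplot.
#' @export
plot_class_areas <- function(areas) {
  check_columns(areas, c("date", "class"), "area table")
  if (!"proportion_pct" %in% names(areas)) {
    areas <- class_proportions(areas)
  }
  ggplot(areas, aes(x = .data$date, y = .data$proportion_pct,
                    fill = .data$class)) +
    geom_col() +
    labs(x = NULL, y = "proportion (%)", fill = NULL) +
    theme_minimal()
}
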