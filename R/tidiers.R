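#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-zone LST ~ FVC fits
#'
#' One row per coastline-distance zone: the OLS slope (kelvin per unit
#' FVC), intercept (kelvin at FVC 0), coefficient of determination and the
#' number of fishnet cells.
#'
#' @param x A [fit_zone_regression()] object.
#' @param ... Unused.
#' @return A tibble with `zone`, `slope`, `intercept`, `slope_se`,
#'   `r_squared`, `n`.
#' @method tidy coastveg_zone_fit
#' @export
tidy.coastveg_zone_fit <- function(x, ...) {
  purrr::imap(x$fits, function(fit, zone) {
    s <- summary(fit)
    tibble(
      zone = zone,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      slope_se = s$coefficients[2, "Std. Error"],
      r_squared = s$r.squared,
      n = length(fit$residuals)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(zone = factor(.data$zone,
                                levels = c("offshore", "middle", "inland"))) |>
    dplyr::arrange(.data$zone)
}

#' One-row summary of a zone-fit set
#'
#' @param x A [fit_zone_regression()] object.
#' @param ... Unused.
#' @return A tibble with the number of zones, total cells, and the range
#'   of fitted slopes.
#' @method glance coastveg_zone_fit
#' @export
glance.coastveg_zone_fit <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_zones = nrow(td),
    n_cells = sum(td$n),
    min_slope = min(td$slope),
    max_slope = max(td$slope)
  )
}
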