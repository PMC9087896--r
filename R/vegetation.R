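#' Compute the normalized difference vegetation index (NDVI)
#'
#' Adds an `ndvi` column computed per pixel as
#' \eqn{(\rho_{nir} - \rho_{red}) / (\rho_{nir} + \rho_{red})} from two
#' reflectance bands. Pixels where either band is missing, or where the
#' denominator is zero (a non-physical reflectance pair), become `NA`.
#' Finite values are clamped into \eqn{[-1, 1]}.
#'
#' @param data A pixel data frame (or a scene from [generate_scene()]) with
#'   red and near-infrared surface reflectance columns in \eqn{[0, 1]}.
#' @param red,nir Unquoted column names of the red and NIR bands.
#' @return `data` as a tibble with an added `ndvi` column.
#' @examples
#' d <- tibble::tibble(red = c(0.5, 0.2, 0), nir = c(0.5, 0.6, 0))
#' compute_ndvi(d)$ndvi  # 0, 0.5, NA
#' @export
compute_ndvi <- function(data, red = red, nir = nir) {
  data <- as_pixel_df(data)
  r <- tryCatch(eval_tidy(enquo(red), data), error = function(e) NULL)
  n <- tryCatch(eval_tidy(enquo(nir), data), error = function(e) NULL)
  if (is.null(r) || is.null(n)) abort("red and NIR bands must both be present")
  denom <- n + r
  ndvi <- ifelse(is.na(denom) | denom == 0, NA_real_, (n - r) / denom)
  dplyr::mutate(as_tibble(data), ndvi = clamp(ndvi, -1, 1))
}

#' Dimidiate pixel model endpoints
#'
#' The dimidiate pixel model treats each pixel as a linear mixture of pure
#' bare soil and pure vegetation; FVC is recovered from NDVI between the two
#' endmember values `soil` (NDVI of pure bare soil) and `veg` (NDVI of full
#' vegetation cover). The defaults 0.06 and 0.6 are the fixed endpoints used
#' for the Qingdao reference analysis.
#'
#' @param soil,veg Endpoint NDVI values; must satisfy `soil < veg`, both in
#'   \eqn{[-1, 1]}.
#' @param provenance Free-form record of where the endpoints came from
#'   (e.g. `"fixed"`, `"quantile:5,95"`).
#' @return An object of class `dimidiate_endpoints`.
#' @seealso [select_endpoints()], [endpoints_from_extremes()]
#' @export
dimidiate_endpoints <- function(soil = 0.06, veg = 0.6, provenance = "fixed") {
  if (!is.numeric(soil) || !is.numeric(veg) || length(soil) != 1 || length(veg) != 1) {
    abort("endpoints must be single numeric values")
  }
  if (!is.finite(soil) || !is.finite(veg) || soil < -1 || veg > 1) {
    abort("endpoints must be finite and within [-1, 1]")
  }
  if (soil >= veg) abort("NDVI_soil must be strictly less than NDVI_veg")
  structure(list(soil = soil, veg = veg, provenance = provenance),
            class = "dimidiate_endpoints")
}

#' @export
print.dimidiate_endpoints <- function(x, ...) {
  cat(sprintf("Dimidiate endpoints: NDVI_soil = %g, NDVI_veg = %g (%s)\n",
              x$soil, x$veg, x$provenance))
  invisible(x)
}

#' Select dimidiate endpoints from the scene NDVI distribution
#'
#' Takes the `lower_pct` and `upper_pct` percentiles of the finite NDVI
#' values (linear interpolation on the sorted values, the usual type-7
#' quantile) as `NDVI_soil` and `NDVI_veg`. This mirrors picking endmembers
#' from an NDVI cumulative-frequency table.
#'
#' @param data Pixel data frame with an NDVI column.
#' @param lower_pct,upper_pct Percentiles in \eqn{[0, 100]} with
#'   `lower_pct < upper_pct`; default 5 and 95.
#' @param ndvi Unquoted NDVI column name.
#' @return A [dimidiate_endpoints()] object with quantile provenance.
#' @export
select_endpoints <- function(data, lower_pct = 5, upper_pct = 95, ndvi = ndvi) {
  data <- as_pixel_df(data)
  v <- eval_tidy(enquo(ndvi), data)
  if (!is.numeric(lower_pct) || !is.numeric(upper_pct) ||
      lower_pct < 0 || upper_pct > 100 || lower_pct >= upper_pct) {
    abort("need 0 <= lower_pct < upper_pct <= 100")
  }
  v <- v[is.finite(v)]
  if (length(v) == 0) abort("NDVI grid has no finite pixels")
  q <- unname(quantile(v, probs = c(lower_pct, upper_pct) / 100, type = 7))
  if (q[1] >= q[2]) {
    abort("degenerate endpoints: the two NDVI quantiles coincide")
  }
  dimidiate_endpoints(q[1], q[2],
                      provenance = sprintf("quantile:%g,%g", lower_pct, upper_pct))
}

#' Dimidiate endpoints from NDVI extremes and known FVC extremes
#'
#' When the minimum and maximum NDVI of an area correspond to known minimum
#' and maximum vegetation cover, the endmember NDVI values can be computed
#' directly:
#' \deqn{NDVI_{soil} = \frac{FVC_{max} NDVI_{min} - FVC_{max} NDVI_{max}}{FVC_{max} - FVC_{min}}}
#' \deqn{NDVI_{veg} = \frac{(1 - FVC_{min}) NDVI_{max} - (1 - FVC_{max}) NDVI_{min}}{FVC_{max} - FVC_{min}}}
#' These are implemented exactly as published. Note that at the limits
#' \eqn{FVC_{min} = 0, FVC_{max} = 1} the soil formula evaluates to
#' \eqn{NDVI_{min} - NDVI_{max}}; the default pipeline therefore uses fixed
#' or quantile endpoints ([dimidiate_endpoints()], [select_endpoints()]) and
#' this estimator is provided as an alternative path only.
#'
#' @param ndvi_min,ndvi_max NDVI extremes, `ndvi_min < ndvi_max`.
#' @param fvc_min,fvc_max FVC extremes, `fvc_min < fvc_max`.
#' @return A [dimidiate_endpoints()] object.
#' @export
endpoints_from_extremes <- function(ndvi_min, ndvi_max, fvc_min, fvc_max) {
  if (fvc_max == fvc_min) abort("fvc_max must differ from fvc_min")
  if (fvc_min > fvc_max) abort("need fvc_min < fvc_max")
  if (ndvi_min >= ndvi_max) abort("need ndvi_min < ndvi_max")
  soil <- (fvc_max * ndvi_min - fvc_max * ndvi_max) / (fvc_max - fvc_min)
  veg <- ((1 - fvc_min) * ndvi_max - (1 - fvc_max) * ndvi_min) / (fvc_max - fvc_min)
  dimidiate_endpoints(soil, veg, provenance = "extremes")
}

#' Invert fractional vegetation cover from NDVI
#'
#' Applies the dimidiate pixel model
#' \eqn{FVC = (NDVI - NDVI_{soil}) / (NDVI_{veg} - NDVI_{soil})} per pixel
#' and clamps the result into \eqn{[0, 1]}: NDVI below the soil endpoint
#' maps to 0, above the vegetation endpoint to 1. `NA` propagates.
#'
#' @param data Pixel data frame with an NDVI column.
#' @param endpoints A [dimidiate_endpoints()] object.
#' @param ndvi Unquoted NDVI column name.
#' @return `data` with an added `fvc` column in \eqn{[0, 1]}.
#' @examples
#' d <- tibble::tibble(ndvi = c(0.06, 0.33, 0.9))
#' compute_fvc(d, dimidiate_endpoints(0.06, 0.6))$fvc  # 0, 0.5, 1
#' @export
compute_fvc <- function(data, endpoints = dimidiate_endpoints(), ndvi = ndvi) {
  data <- as_pixel_df(data)
  if (!inherits(endpoints, "dimidiate_endpoints")) {
    abort("endpoints must be a dimidiate_endpoints object")
  }
  v <- eval_tidy(enquo(ndvi), data)
  fvc <- (v - endpoints$soil) / (endpoints$veg - endpoints$soil)
  out <- dplyr::mutate(as_tibble(data), fvc = clamp(fvc, 0, 1))
  attr(out, "endpoints") <- endpoints
  out
}

#' Classify FVC into the five cover classes
#'
#' Bins FVC into bare land and water (`BL&W`, \eqn{[0, 0.2)}), low
#' (`L-FVC`, \eqn{[0.2, 0.4)}), secondary low (`SL-FVC`, \eqn{[0.4, 0.6)}),
#' medium (`M-FVC`, \eqn{[0.6, 0.8)}) and high cover (`H-FVC`,
#' \eqn{[0.8, 1]}). Bins are lower-inclusive with the top bin closed, so the
#' five classes partition \eqn{[0, 1]} exactly; `NA` propagates.
#'
#' @param data Pixel data frame with an `fvc` column in \eqn{[0, 1]}.
#' @param fvc Unquoted FVC column name.
#' @return `data` with an added `fvc_class` factor column
#'   (levels [fvc_class_levels()]).
#' @export
classify_fvc <- function(data, fvc = fvc) {
  data <- as_pixel_df(data)
  v <- eval_tidy(enquo(fvc), data)
  if (any(v < 0 | v > 1, na.rm = TRUE)) abort("FVC values must lie in [0, 1]")
  idx <- findInterval(v, c(0.2, 0.4, 0.6, 0.8)) + 1L
  dplyr::mutate(as_tibble(data),
                fvc_class = factor(fvc_class_levels()[idx],
                                   levels = fvc_class_levels()))
}

#' Per-class area and proportion table
#'
#' Counts pixels per class, converts counts to areas (pixel count times the
#' pixel area) and to proportions of the total classified (non-`NA`) area.
#' Works for both FVC classes and mean-SD temperature zones — any factor
#' column whose levels define the classes. Levels absent from the data get a
#' zero-area row, so the table always partitions the classified area.
#'
#' @param data Pixel data frame with a class factor column.
#' @param class Unquoted class column name (e.g. `fvc_class` or `zone`).
#' @param cell_area_km2 Area of one pixel in km² (e.g. `0.09` for 300 m
#'   cells); must be positive.
#' @param date,season Optional scene tags copied into the table.
#' @return A tibble with columns `date`, `season` (if given), `class`,
#'   `area_km2`, `proportion_pct`, plus attribute `total_km2`.
#' @export
class_area_table <- function(data, class, cell_area_km2,
                             date = NULL, season = NULL) {
  data <- as_pixel_df(data)
  if (!is.numeric(cell_area_km2) || cell_area_km2 <= 0) {
    abort("cell_area_km2 must be a positive number")
  }
  cl <- eval_tidy(enquo(class), data)
  cl <- cl[!is.na(cl)]
  if (length(cl) == 0) abort("all pixels are NoData: nothing to tabulate")
  if (!is.factor(cl)) cl <- factor(cl)
  counts <- table(cl)
  area <- as.numeric(counts) * cell_area_km2
  out <- tibble(
    class = factor(names(counts), levels = levels(cl)),
    area_km2 = area,
    proportion_pct = 100 * area / sum(area)
  )
  if (!is.null(season)) out <- dplyr::mutate(out, season = season, .before = 1)
  if (!is.null(date)) out <- dplyr::mutate(out, date = date, .before = 1)
  attr(out, "total_km2") <- sum(area)
  out
}

#' Recompute class proportions from printed areas
#'
#' Given a long table of per-class areas (one or more scenes), recomputes
#' each class's percentage of its scene-and-segmentation total, rounded to
#' two decimals at this reporting boundary. Used to audit published
#' area-accounting tables.
#'
#' @param areas A data frame with columns `class` and `area_km2`, plus any
#'   grouping columns named in `by` (default `date` and `segmentation`
#'   when present).
#' @param by Character vector of grouping columns; defaults to those of
#'   `c("date", "season", "segmentation")` present in `areas`.
#' @param digits Rounding applied to the reported proportions (default 2).
#' @return `areas` with added `proportion_pct` and `total_km2` columns.
#' @export
class_proportions <- function(areas, by = NULL, digits = 2) {
  check_columns(areas, c("class", "area_km2"), "area table")
  if (any(areas$area_km2 < 0, na.rm = TRUE)) abort("areas must be nonnegative")
  by <- by %||% intersect(c("date", "season", "segmentation"), names(areas))
  out <- areas |>
    as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(total_km2 = sum(.data$area_km2),
                  proportion_pct = round(100 * .data$area_km2 / .data$total_km2,
                                         digits)) |>
    dplyr::ungroup()
  out
}
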