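#' Min-max normalize an LST grid
#'
#' Rescales the finite LST values to \eqn{[0, 1]} for cross-scene display.
#' Mean-SD temperature zoning is invariant under positive affine transforms,
#' so classifying the normalized grid gives exactly the same zone map as
#' classifying the raw grid; normalization is kept for comparability of
#' maps, not needed for classification.
#'
#' @param data Pixel data frame with an LST column.
#' @param lst Unquoted LST column name.
#' @return `data` with an added `lst_norm` column.
#' @export
normalize_lst <- function(data, lst = lst_k) {
  data <- as_pixel_df(data)
  v <- eval_tidy(enquo(lst), data)
  fin <- v[is.finite(v)]
  if (length(fin) < 2) abort("need at least two finite LST pixels")
  rng <- range(fin)
  if (rng[1] == rng[2]) abort("degenerate normalization: LST grid is constant")
  dplyr::mutate(as_tibble(data), lst_norm = (v - rng[1]) / (rng[2] - rng[1]))
}

#' Scene mean and standard deviation of LST
#'
#' The two statistics driving mean-SD temperature zoning, computed over the
#' finite pixels. The standard deviation uses the population convention
#' (divide by n): it describes the whole scene, not a sample from it.
#'
#' @param data Pixel data frame with an LST column.
#' @param lst Unquoted LST column name.
#' @return A one-row tibble with `mu`, `std` and `n`.
#' @export
mean_sd_params <- function(data, lst = lst_k) {
  data <- as_pixel_df(data)
  v <- eval_tidy(enquo(lst), data)
  v <- v[is.finite(v)]
  if (length(v) < 2) abort("need at least two finite LST pixels")
  tibble(mu = mean(v), std = sqrt(mean((v - mean(v))^2)), n = length(v))
}

#' Mean-SD temperature zoning
#'
#' Classifies LST into five temperature zones around the scene mean
#' \eqn{\mu} and standard deviation \eqn{std}:
#' \itemize{
#'   \item HTZ: \eqn{LST > \mu + std}
#'   \item SHTZ: \eqn{\mu + 0.5 std < LST \le \mu + std}
#'   \item MTZ: \eqn{\mu - 0.5 std < LST \le \mu + 0.5 std}
#'   \item SLTZ: \eqn{\mu - std < LST \le \mu - 0.5 std}
#'   \item LTZ: \eqn{LST \le \mu - std}
#' }
#' The bottom interval is closed so the five zones tile the line. A
#' constant grid (std = 0) yields all-MTZ with a warning. Because the
#' thresholds are affine in \eqn{(\mu, std)}, the zone map is invariant
#' under positive affine transforms of the grid.
#'
#' @param data Pixel data frame with an LST column.
#' @param lst Unquoted LST column name.
#' @return `data` with an added `zone` factor column (levels
#'   [lst_zone_levels()], coldest first) and a `mean_sd` attribute holding
#'   the [mean_sd_params()] row.
#' @export
classify_mean_sd <- function(data, lst = lst_k) {
  data <- as_pixel_df(data)
  v <- eval_tidy(enquo(lst), data)
  if (sum(is.finite(v)) < 2) abort("need at least two finite LST pixels")
  ms <- mean_sd_params(dplyr::tibble(lst_k = v))
  mu <- ms$mu
  s <- ms$std
  if (s == 0) {
    warn("LST grid is constant (std = 0): all pixels assigned to MTZ")
    zone <- ifelse(is.finite(v), "MTZ", NA_character_)
  } else {
    zone <- dplyr::case_when(
      !is.finite(v) ~ NA_character_,
      v > mu + s ~ "HTZ",
      v > mu + 0.5 * s ~ "SHTZ",
      v > mu - 0.5 * s ~ "MTZ",
      v > mu - s ~ "SLTZ",
      TRUE ~ "LTZ"
    )
  }
  out <- dplyr::mutate(as_tibble(data),
                       zone = factor(zone, levels = lst_zone_levels()))
  attr(out, "mean_sd") <- ms
  out
}

#' Urban heat island ratio index (URI)
#'
#' A weighted sum of temperature-zone area percentages,
#' \eqn{URI = \frac{1}{100 m} \sum_{i=1}^{m} \omega_i p_i}, with m = 5
#' grades and weights 5, 4, 3, 2, 1 for HTZ, SHTZ, MTZ, SLTZ and LTZ.
#' When the five proportions sum to 100, URI lies in \eqn{[0.2, 1]}; larger
#' values mean more area in the hot zones and a stronger heat island.
#'
#' @param p Zone proportions in percent: either a [class_area_table()]
#'   (data frame with `class` and `proportion_pct`), a named numeric
#'   vector (names among the zone labels), or an unnamed numeric vector of
#'   five values ordered HTZ, SHTZ, MTZ, SLTZ, LTZ.
#' @return The URI as a single number.
#' @examples
#' compute_uri(c(HTZ = 100, SHTZ = 0, MTZ = 0, SLTZ = 0, LTZ = 0))  # 1
#' compute_uri(rep(20, 5))                                          # 0.6
#' @export
compute_uri <- function(p) {
  w <- uri_weights()
  if (is.data.frame(p)) {
    check_columns(p, c("class", "proportion_pct"), "zone table")
    props <- setNames(p$proportion_pct, as.character(p$class))
  } else if (is.numeric(p) && !is.null(names(p))) {
    props <- p
  } else if (is.numeric(p) && length(p) == length(w)) {
    props <- setNames(p, names(w))
  } else {
    abort("p must be a zone table, a named vector, or five ordered proportions")
  }
  unknown <- setdiff(names(props), names(w))
  if (length(unknown) > 0) {
    abort(sprintf("unknown zone label(s): %s", paste(unknown, collapse = ", ")))
  }
  if (any(props < 0)) abort("zone proportions must be nonnegative")
  if (sum(props) > 100 + 1e-6) abort("zone proportions exceed 100%")
  sum(w[names(props)] * props) / (100 * length(w))
}

#' Per-scene URI trend table
#'
#' Computes per-scene temperature-zone proportions and the URI from a
#' stacked zone-area table covering several acquisition dates, for
#' inspecting how the heat island evolves by season.
#'
#' @param areas Long data frame with columns `date` (e.g. `"2009.07"`),
#'   `season`, `class` (zone labels) and `area_km2`.
#' @return A tibble of class `coastveg_uri_trend`: one row per scene with
#'   `date`, `season`, `year` (decimal), `p_htz` … `p_ltz` and `uri`.
#' @seealso [uri_trend_slopes()] for per-season least-squares trends.
#' @export
uri_trend <- function(areas) {
  check_columns(areas, c("date", "season", "class", "area_km2"), "area table")
  out <- areas |>
    as_tibble() |>
    dplyr::group_by(.data$date, .data$season) |>
    dplyr::summarise(
      uri = compute_uri(setNames(100 * .data$area_km2 / sum(.data$area_km2),
                                 as.character(.data$class))),
      p = list(setNames(100 * .data$area_km2 / sum(.data$area_km2),
                        paste0("p_", tolower(as.character(.data$class))))),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("p") |>
    dplyr::mutate(year = decimal_year(.data$date), .after = "season") |>
    dplyr::arrange(.data$year)
  class(out) <- c("coastveg_uri_trend", class(out))
  out
}

# "YYYY.MM" -> decimal year at mid-month
decimal_year <- function(date) {
  parts <- strsplit(as.character(date), ".", fixed = TRUE)
  vapply(parts, function(p) {
    yr <- suppressWarnings(as.numeric(p[1]))
    mo <- if (length(p) > 1) suppressWarnings(as.numeric(p[2])) else 1
    if (is.na(yr)) abort(sprintf("cannot parse date '%s' as YYYY.MM",
                                 paste(p, collapse = ".")))
    yr + (ifelse(is.na(mo), 1, mo) - 0.5) / 12
  }, numeric(1))
}

#' Per-season least-squares URI trend slopes
#'
#' Fits `uri ~ year` by ordinary least squares within each season of a
#' [uri_trend()] table. With a single scene in a season the slope is
#' reported as `NA`.
#'
#' @param trend A [uri_trend()] table (or any data frame with `season`,
#'   `year` and `uri` columns).
#' @return A tibble with `season`, `slope` (URI per year) and `n`.
#' @export
uri_trend_slopes <- function(trend) {
  check_columns(trend, c("season", "year", "uri"), "trend table")
  trend |>
    as_tibble() |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(
      slope = if (dplyr::n() >= 2 && stats::var(.data$year) > 0) {
        unname(coef(lm(uri ~ year, data = dplyr::pick(dplyr::everything())))[2])
      } else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
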