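#' @importFrom rlang %||% abort warn enquo eval_tidy as_name .data :=
#' @importFrom dplyr mutate filter group_by summarise ungroup arrange select
#'   bind_rows left_join n count across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats lm coef quantile rnorm runif sd setNames complete.cases
NULL

# clamp a numeric vector into [lo, hi], leaving NA untouched
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# accept either a pixel tibble or a full scene object
as_pixel_df <- function(data) {
  if (inherits(data, "coastveg_scene")) data$pixels else data
}

check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

#' Class labels used throughout the pipeline
#'
#' `fvc_class_levels()` returns the five fractional-vegetation-cover class
#' labels from bare land and water (`BL&W`) up to high cover (`H-FVC`);
#' `lst_zone_levels()` returns the five mean-SD temperature zones from the
#' low-temperature zone (`LTZ`) up to the high-temperature zone (`HTZ`).
#'
#' @return A character vector of five labels, ordered from low to high.
#' @export
fvc_class_levels <- function() c("BL&W", "L-FVC", "SL-FVC", "M-FVC", "H-FVC")

#' @rdname fvc_class_levels
#' @export
lst_zone_levels <- function() c("LTZ", "SLTZ", "MTZ", "SHTZ", "HTZ")

# URI weights, hottest zone heaviest
uri_weights <- function() c(HTZ = 5, SHTZ = 4, MTZ = 3, SLTZ = 2, LTZ = 1)
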