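#' Write a pixel column as an ESRI ASCII grid
#'
#' Serializes one value column of a pixel table to the plain-text ESRI
#' ASCII grid format (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/
#' `NODATA_value` header followed by rows north to south). `NA` pixels are
#' written as the NoData sentinel.
#'
#' @param data Pixel data frame with `row`, `col`, `x`, `y` columns.
#' @param path Output file path.
#' @param value Unquoted name of the column to write.
#' @param nodata NoData sentinel (default -9999).
#' @param digits Significant digits to print (default 10).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(data, path, value, nodata = -9999, digits = 10) {
  data <- as_pixel_df(data)
  check_columns(data, c("row", "col", "x", "y"), "pixel table")
  v <- eval_tidy(enquo(value), data)
  nr <- max(data$row)
  nc <- max(data$col)
  if (nrow(data) != nr * nc) abort("pixel table is not a complete grid")
  cell <- attr(data, "cell_size", exact = TRUE) %||% infer_cell_size(data$x)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(data$row, data$col)] <- v
  m[is.na(m)] <- nodata
  header <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.6f", min(data$x) - cell / 2),
    sprintf("yllcorner %.6f", min(data$y) - cell / 2),
    sprintf("cellsize %.6f", cell),
    sprintf("NODATA_value %g", nodata)
  )
  # row 1 of the file is the northernmost (largest y = largest row index)
  body <- apply(m[rev(seq_len(nr)), , drop = FALSE], 1,
                function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid into a pixel tibble
#'
#' @param path File written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @param value Name for the value column (default `"value"`).
#' @return A tibble with `row`, `col`, `x`, `y` and the value column;
#'   NoData pixels are `NA`. Carries a `cell_size` attribute.
#' @export
read_ascii_grid <- function(path, value = "value") {
  lines <- readLines(path)
  header <- lines[1:6]
  hv <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), header, ignore.case = TRUE, value = TRUE)
    if (length(ln) == 0) abort(sprintf("malformed ASCII grid: missing %s", key))
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  nc <- as.integer(hv("ncols")); nr <- as.integer(hv("nrows"))
  xll <- hv("xllcorner"); yll <- hv("yllcorner")
  cell <- hv("cellsize"); nodata <- hv("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) abort("ASCII grid body does not match header")
  m <- matrix(vals, nr, nc, byrow = TRUE)[rev(seq_len(nr)), , drop = FALSE]
  m[m == nodata] <- NA_real_
  out <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc)) |>
    dplyr::mutate(x = xll + (.data$col - 0.5) * cell,
                  y = yll + (.data$row - 0.5) * cell,
                  !!value := m[cbind(row, col)])
  attr(out, "cell_size") <- cell
  out
}

#' Coastline GeoJSON I/O
#'
#' Writes a [coastline()] polyline as a GeoJSON `LineString` feature, and
#' reads one back. Coordinates are kept in the projected CRS of the
#' analysis (meters); the CRS identifier, when present, travels in the
#' feature properties.
#'
#' @param coast A [coastline()] object.
#' @param path GeoJSON file path.
#' @return `write_coastline_geojson()` returns `path` invisibly;
#'   `read_coastline_geojson()` returns a [coastline()].
#' @export
write_coastline_geojson <- function(coast, path) {
  check_columns(coast, c("x", "y"), "coastline")
  gj <- list(
    type = "Feature",
    geometry = list(
      type = "LineString",
      coordinates = unname(Map(c, coast$x, coast$y))
    ),
    properties = list(crs = attr(coast, "crs", exact = TRUE))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_coastline_geojson
#' @export
read_coastline_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- if (identical(gj$type, "Feature")) gj$geometry else gj
  if (!identical(geom$type, "LineString")) {
    abort("expected a GeoJSON LineString coastline")
  }
  xy <- do.call(rbind, lapply(geom$coordinates, function(p) {
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))
  }))
  coastline(xy[, 1], xy[, 2], crs = gj$properties$crs)
}

#' Packaged reference class-area table
#'
#' Loads the packaged seasonal class-area accounting for a ~6,300 km²
#' coastal study area: ten acquisitions (five summer, five winter,
#' 2000–2020), each with per-class areas in km² for both the
#' five-class FVC segmentation and the five mean-SD LST zones.
#'
#' @param path Optional path to an alternative CSV with columns `season`,
#'   `date`, `segmentation`, `class`, `area_km2`.
#' @return A long tibble with those five columns.
#' @seealso [class_proportions()] to recompute the per-scene percentages.
#' @export
reference_class_areas <- function(path = NULL) {
  path <- path %||% system.file("extdata", "seasonal_class_areas.csv",
                                package = "coastveg", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           season = readr::col_character(),
                           date = readr::col_character(),
                           segmentation = readr::col_character(),
                           class = readr::col_character(),
                           area_km2 = readr::col_double()
                         ))
  bad <- !out$class %in% c(fvc_class_levels(), lst_zone_levels())
  if (any(bad)) {
    abort(sprintf("malformed area table: unknown class in row(s) %s",
                  paste(utils::head(which(bad)), collapse = ", ")))
  }
  if (any(is.na(out$area_km2) | out$area_km2 < 0)) {
    abort("malformed area table: missing or negative area")
  }
  out
}
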