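# shared builders for small synthetic inputs

tiny_spec <- function(seed = 1, season = "summer", ...) {
  landscape_spec(rows = 32, cols = 48, cell_size = 300, seed = seed,
                 season = season, ...)
}

# a straight north-south coastline at x = x0
straight_coast <- function(x0 = 0, y_min = -1e5, y_max = 1e5) {
  coastline(c(x0, x0), c(y_min, y_max))
}

# run the vegetation + thermal chain on a scene with its own parameters
recover_scene <- function(sc) {
  sc |>
    compute_ndvi() |>
    compute_fvc(sc$endpoints) |>
    classify_fvc() |>
    retrieve_lst(sc$sensor, sc$atm)
}

# a complete rectangular pixel grid with given value columns
pixel_grid <- function(nr, nc, cell = 100, ...) {
  g <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc)) |>
    dplyr::mutate(x = (col - 0.5) * cell, y = (row - 0.5) * cell, ...)
  attr(g, "cell_size") <- cell
  g
}
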