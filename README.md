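# coastveg

Vegetation cover, land surface temperature and heat-island analysis for
coastal cities, as a tidy raster pipeline in R.

Urban vegetation cools the land surface, but in a coastal city the sea
moderates that relationship: near the shore, marine air and sea–land
winds dampen the cooling signal of vegetation, while far inland it is
strongest. `coastveg` is for remote-sensing ecologists and urban-climate
analysts who want to quantify that interaction from Landsat-like imagery:
it computes fractional vegetation cover (FVC), retrieves land surface
temperature (LST), summarises the urban heat island, and stratifies the
LST–FVC relationship by distance to the coastline. A synthetic
coastal-scene generator with known ground truth makes the whole chain
testable end to end without external data.

## The models

**Fractional vegetation cover** comes from NDVI via the dimidiate pixel
model — each pixel a linear mix of pure soil and pure vegetation:

```
NDVI = (ρ_nir − ρ_red) / (ρ_nir + ρ_red)
FVC  = (NDVI − NDVI_soil) / (NDVI_veg − NDVI_soil),  clamped to [0, 1]
```

with endpoints either fixed (default 0.06 / 0.6) or taken as scene NDVI
percentiles. FVC is binned into five classes from bare land and water
(`BL&W`, 0–0.2) up to high cover (`H-FVC`, 0.8–1).

**Land surface temperature** uses the single-band radiative transfer
method: DN → radiance by linear calibration, then

```
B(T_s) = ((L_sen − L_u)/τ − (1 − ε)·L_d) / ε
T_s    = K2 / ln(K1 / B(T_s) + 1)
```

with per-scene atmospheric parameters (τ, L_u, L_d), an FVC-driven
two-value emissivity, and the sensor's thermal constants K1, K2.

**Heat island**: LST is classified into five zones around the scene mean
μ and standard deviation *std* (HTZ above μ+std down to LTZ at or below
μ−std), and summarised by the heat-island ratio index

```
URI = (1 / 100m) Σ ωᵢ pᵢ ,   m = 5,  ω = 5,4,3,2,1 (HTZ…LTZ)
```

which lies in [0.2, 1] and grows as area shifts into the hot zones.

**Coastal stratification**: FVC and LST are averaged on a fishnet grid,
cells are labelled offshore (≤10 km), middle (10–25 km) or inland
(>25 km) by distance to the coastline, and mean LST is regressed on mean
FVC within each zone; the slope (K per unit FVC) measures vegetation's
cooling effect there.

## Worked example

```r
library(coastveg)

scene <- generate_scene(landscape_spec(season = "summer", seed = 42),
                        date = "2020.06")
pixels <- scene |>
  compute_ndvi() |>
  compute_fvc(scene$endpoints) |>
  classify_fvc() |>
  retrieve_lst(scene$sensor, scene$atm) |>
  classify_mean_sd()

class_area_table(pixels, fvc_class, cell_area_km2 = 0.09)
#> # A tibble: 5 × 3
#>   class  area_km2 proportion_pct
#>   <fct>     <dbl>          <dbl>
#> 1 BL&W       393.           40.1
#> 2 L-FVC        0             0
#> 3 SL-FVC     114.           11.6
#> 4 M-FVC      229.           23.4
#> 5 H-FVC      243.           24.8

round(compute_uri(class_area_table(pixels, zone, cell_area_km2 = 0.09)), 3)
#> [1] 0.594

net <- build_fishnet(pixels, scene$coastline, cell_length = 900)
tidy(fit_zone_regression(net))
#> # A tibble: 3 × 6
#>   zone     slope intercept slope_se r_squared     n
#>   <fct>    <dbl>     <dbl>    <dbl>     <dbl> <int>
#> 1 offshore -2.98      303.   0.0566     0.883   370
#> 2 middle   -4.44      304.   0.0444     0.948   551
#> 3 inland   -6.07      306.   0.131      0.879   298

validate_lst(pixels, generate_stations(scene, n = 15, noise_sd = 2, seed = 1))
#> # A tibble: 1 × 3
#>   mae_k rmse_k     n
#> 1  1.03   1.23    15
```

Reading the output: a quarter of this synthetic summer scene is high
vegetation cover; the URI of 0.594 says the hot zones hold somewhat more
than a uniform share of the area; and the fitted cooling slopes steepen
from −2.98 K per unit FVC offshore to −6.07 K inland — the coastal
gradient the package is built to detect (the scene was constructed with
slopes −3 / −4.5 / −6, so the fit recovers the truth within its standard
errors). The station check compares retrieved LST against 15 synthetic
station records with 2 K observation noise.

The package also ships a reference seasonal class-area table for a
~6,300 km² coastal study area (`reference_class_areas()`), from which
`class_proportions()` and `uri_trend()` recompute per-scene class
percentages and URI values. Plot methods (`autoplot()` on scenes, zone
fits and URI trends, `plot_class_areas()`) give quick-look figures, and
`run_pipeline()` / `read_pipeline_config()` drive multi-scene batches
from a YAML config (a thin CLI wrapper lives in `inst/cli/coastveg.R`).

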