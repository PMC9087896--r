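---
title: "Methods: vegetation cover, land surface temperature and the coastal heat island"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vegetation cover, land surface temperature and the coastal heat island}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastveg)
library(dplyr)
```

`coastveg` implements a complete remote-sensing workflow for asking how
urban vegetation moderates the thermal environment of a coastal city:
fractional vegetation cover (FVC) from NDVI, land surface temperature
(LST) from a thermal band, heat-island zoning and the URI summary
statistic, and a coastline-distance stratification of the LST–FVC
relationship. This vignette explains each model, the tunable parameters,
the numerical conventions, and what the synthetic-scene generator does and
does not emulate.

## The dimidiate pixel model

NDVI is the usual band ratio
$NDVI = (\rho_{nir} - \rho_{red}) / (\rho_{nir} + \rho_{red})$, clamped to
$[-1, 1]$; a pixel whose two reflectances sum to zero has no defined ratio
and is treated as NoData rather than an error, since such a pair is not a
physical land reflectance.

The dimidiate pixel model treats every pixel as a linear mixture of two
endmembers — pure bare soil with index $NDVI_{soil}$ and full vegetation
cover with index $NDVI_{veg}$ — so the cover fraction is

$$FVC = \frac{NDVI - NDVI_{soil}}{NDVI_{veg} - NDVI_{soil}},$$

clamped into $[0, 1]$. Clamping, rather than masking, is deliberate: NDVI
beyond the endpoints is expected whenever the endpoints are percentile
estimates, and a cover fraction outside $[0, 1]$ has no meaning.

Endpoints can be supplied three ways:

* **fixed** (`dimidiate_endpoints(0.06, 0.6)`, the default) — the pair
  used for the packaged coastal study area;
* **scene quantiles** (`select_endpoints()`, default 5th/95th
  percentile) — percentiles of the finite NDVI values, using linear
  interpolation on the sorted sample (R's type-7 quantile). The
  interpolation rule is stated because cumulative-frequency tables admit
  several conventions and tests need an exact one;
* **from extremes** (`endpoints_from_extremes()`) — the closed-form
  estimator from NDVI extremes and known FVC extremes, implemented exactly
  as published. At the limits $FVC_{min}=0, FVC_{max}=1$ its soil formula
  degenerates to $NDVI_{min} - NDVI_{max}$, which is why the default
  pipeline never uses this path; it is provided for completeness.

FVC is binned into five classes — `BL&W` $[0,0.2)$, `L-FVC` $[0.2,0.4)$,
`SL-FVC` $[0.4,0.6)$, `M-FVC` $[0.6,0.8)$, `H-FVC` $[0.8,1]$. The
published class labels overlap at the bin edges ("0–0.2", "0.2–0.4", …),
so a convention was needed: bins are lower-inclusive with the top bin
closed, making the five classes an exact partition of $[0,1]$.

## LST retrieval

The thermal chain is the single-band radiative transfer method. At-sensor
radiance is recovered from digital numbers by the sensor's linear
calibration $L = g \cdot DN + b$; the radiative transfer equation

$$L_{sen} = \left(\varepsilon B(T_s) + (1 - \varepsilon) L_d\right)\tau + L_u$$

is solved for the surface blackbody radiance $B(T_s)$; and temperature
follows from the band-effective inverse Planck relation
$T_s = K_2 / \ln(K_1 / B + 1)$. The atmospheric terms — transmissivity
$\tau$, upwelling radiance $L_u$, downwelling radiance $L_d$ — are
per-scene configuration, as produced by an atmospheric-correction
calculator; the package does not estimate them. Three sensor profiles ship
with the published thermal constants of the Landsat TM, ETM+ and
TIRS families (for the TIRS-like default, $K_1 = 774.8853$,
$K_2 = 1321.0789$ K).

Two conventions matter numerically:

* everything internal is **kelvin**; degrees Celsius exist only at the
  reporting boundary, because the Planck relation is kelvin-native;
* retrieved temperatures outside the plausibility bounds (default
  $[220, 340]$ K) are masked to NoData instead of raising, so one
  degenerate pixel cannot abort a batch run. Nonpositive surface radiance
  (sensor radiance at or below the atmospheric path term) likewise maps
  to NoData.

Emissivity is the one input the workflow must invent: the minimal scheme
consistent with what the pipeline already computes is a two-endmember map
driven by FVC — $\varepsilon_v = 0.986$ where $FVC \ge 0.5$,
$\varepsilon_s = 0.964$ elsewhere (`emissivity_from_fvc()`), with constant
and per-pixel overrides. This is documented as a gap-fill, not a claim
about the best emissivity model.

Station validation (`validate_lst()`) matches each station to the nearest
pixel center — point sampling, the simplest defensible convention when
station footprints are unknown — and reports MAE and RMSE of predicted
minus observed temperature.

## Heat-island zoning and the URI

LST is classified into five zones around the scene mean $\mu$ and
standard deviation $std$: HTZ above $\mu + std$, then SHTZ, MTZ, SLTZ in
half-$std$ steps, and LTZ at or below $\mu - std$. Three choices are
documented because tests depend on them:

* $std$ uses the **population** formula (divide by $n$): the statistic
  describes the whole scene, not a sample;
* the published interval table leaves the value exactly $\mu - std$
  unassigned; it is placed in LTZ so the five intervals tile the line;
* because all thresholds are affine in $(\mu, std)$, the zone map is
  invariant under positive affine transforms of the grid. Min-max
  normalization (`normalize_lst()`) is therefore retained for map
  comparability but the classification path consumes raw LST.

The heat-island ratio index is
$URI = \frac{1}{100\,m}\sum_{i=1}^{m}\omega_i p_i$ with $m = 5$ grades,
weights $5,4,3,2,1$ from HTZ down to LTZ, and $p_i$ the zone area
percentages, computed over the same pixel universe as the area table
(NoData excluded from numerator and denominator). With proportions
summing to 100, URI is bounded in $[0.2, 1]$ and strictly increases when
area moves to a hotter zone.

## Coastline-distance stratification

Distance to the coast is the Euclidean distance from a point to the
nearest point of the coastline polyline, in km, with three bands:
offshore $\le 10$ km, middle $(10, 25]$ km, inland $> 25$ km (the bounds
read literally from their definitions, both upper bounds inclusive).

Aggregation uses a fishnet of axis-aligned squares snapped to the raster
origin. A pixel belongs to the cell containing its center, which lets any
cell length at least as large as the pixel size be used — the canonical
100 m fishnet over 30 m pixels is itself not an integer multiple, so
exact nesting cannot be a requirement. A cell is retained when its count
of valid pixels (both FVC and LST non-NoData) reaches `min_valid_frac`
(default 0.5) of the expected pixel count; the floor prevents one-pixel
cells from dominating fits. Means are taken over the jointly valid
pixels so the FVC and LST of a cell always describe the same ground.
Each retained cell is assigned a zone from its center distance — a single
representative point is adequate for 100 m cells against multi-km zone
widths.

Per zone, mean LST is regressed on mean FVC by ordinary least squares
(`fit_zone_regression()`, with `tidy()`/`glance()`/`autoplot()` methods).
OLS rather than robust or weighted variants matches the simple linear
fits this kind of analysis reports; slopes are in kelvin per unit FVC
(identical in °C per unit FVC).

## The synthetic-scene generator

Real multi-decade Landsat archives cannot ship with a package, so every
downstream stage is exercised on synthetic coastal scenes with known
truth (`landscape_spec()`, `generate_scene()`). The design principle is
*manufactured consistency*: the forward model is the exact inverse of the
analysis chain. A true FVC field is laid out, mapped through the
configured endpoints to NDVI, and realized as a red/NIR pair satisfying
that NDVI; a true LST field is pushed through the Planck function and the
radiative transfer equation to an at-sensor thermal band. The pipeline
run with the same parameters must then recover the truth to numerical
precision ($10^{-9}$ for FVC, $10^{-6}$ K for LST), which makes the
recovery tests sharp and tolerance-free.

The landscape emulates the structure of a coastal hilly city: water
seaward of a piecewise-linear shoreline, forested mountains near the
coast, an urban belt, agriculture inland and scattered bare ground. Cover
classes are banded by blurred coast distance so each distance zone
contains a spread of FVC. Class FVC ranges (summer) are forest
0.82–0.98, agriculture 0.50–0.80, urban 0.02–0.20, bare 0.00–0.12 —
typical of dense temperate forest, cropland, built-up and bare surfaces.
In winter the deciduous canopy fraction (default 0.5) and crops lose
foliage, so a winter scene always has lower mean FVC than its summer
twin.

True LST is linear in FVC within each coastline-distance zone, with
summer slopes $(-3, -4.5, -6)$ K per unit FVC for offshore/middle/inland
and intercepts near 303–305.5 K, winter slopes 0 near 277 K, and pixel
noise of 0.5 K. The summer values encode the qualitative finding the
package is built to detect — vegetation cools, and cools more steeply
far from the moderating sea — at magnitudes inside the ranges such
analyses report; winter encodes the near-flat off-season relationship.
These are study conditions, not tuning knobs.

Default scenes are 96×128 pixels at 300 m. The coarse cell keeps a desk
scale grid spanning ~38 km inland so all three distance zones are
populated; tests and the acceptance script use this size (plus one
128×128 scene and 30–100 seeded replicates), which keeps the full suite
under a minute.

The generator stores the thermal band as **unquantized** DN by default.
Rounding to 16-bit integers (available via `quantize = TRUE`) is more
faithful to an archive but injects ~$10^{-3}$ K of quantization error,
which would turn the exact recovery contract into a tolerance judgment;
the quantized path is tested separately against a one-DN-step bound.

What the generator does **not** emulate: atmospheric or sensor noise in
the reflective bands, clouds, scan-line artifacts, topographic
illumination, spatially varying atmosphere, mixed-pixel emissivity, or
any deviation of the true mixing model from the dimidiate assumption.
Passing recovery tests therefore demonstrates the correctness and
self-consistency of the implementation, not the accuracy of the dimidiate
or single-band methods on real imagery — that accuracy is bounded by the
usual station-validation errors of several kelvin.

Stations are sampled at pixel centers (point sampling) with Gaussian
noise; the footprint-matching rule for real stations is unknown, and
point sampling is the convention the generator documents.

## Reference area table

`reference_class_areas()` loads a packaged class-area accounting for a
~6,300 km² coastal study area: ten acquisitions (2000–2020, five summer
and five winter) with per-class areas for both the FVC segmentation and
the LST zones. `class_proportions()` recomputes each class's percentage
of its scene total (rounding to two decimals only at this reporting
boundary), and `uri_trend()` turns the LST rows into per-scene URI
values:

```{r}
ref <- reference_class_areas()
class_proportions(ref) |>
  filter(date == "2020.06", segmentation == "fvc")
uri_trend(filter(ref, segmentation == "lst"))
```

Note that the areas are reported to two decimals and per-scene totals
vary (NoData bookkeeping differs between acquisitions), so quantities
derived from this table inherit those rounding and masking conventions;
the package recomputes everything from the areas as given.

## Known limitations

* Distances are planar Euclidean in a projected CRS; no geodesic option.
* The fishnet assigns pixels by center membership; pixels straddling cell
  edges are not split.
* OLS zone fits ignore spatial autocorrelation between neighbouring
  fishnet cells, as the analyses they mirror do; standard errors are
  optimistic in that respect.
* The emissivity scheme is a two-value gap-fill, not a retrieval.
* The URI depends on the pixel universe over which zone proportions are
  taken; published tables do not always state theirs, so cross-study URI
  comparisons should recompute from areas, as `uri_trend()` does.
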