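---
title: "Land use regression for ambient ozone: models, buffers, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land use regression for ambient ozone: models, buffers, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lurkit)
```

## The modelling problem

Land use regression (LUR) estimates the fine-scale spatial variability of an
air pollutant by regressing concentrations measured at a monitoring network on
quantitative descriptions of each site's surroundings, then predicting at
unmonitored locations. For ozone — a secondary pollutant formed from NOx and
volatile organics in sunlight and destroyed by fresh NO near sources — the
useful predictors are a mix of

* **buffer variables**: a geographic layer summarised inside a circular disk
  of radius $r$ around the site (count of landmark points such as temples,
  length of road, area of residential/industrial/forest/crop polygons, mean
  of a greenness raster such as NDVI), evaluated on a ladder of radii from
  25 m to 5000 m;
* **distance variables**: Euclidean distance to the nearest point source
  (power plant, incinerator);
* **station covariates**: co-measured NOx, temperature, relative humidity and
  site altitude.

The model is ordinary least squares,

$$ y_{st} = \beta_0 + \sum_j \beta_j x_{j,st} + \varepsilon_{st}, $$

for station $s$ and period $t$ (annual means), with predictors chosen by a
*supervised* forward selection: every candidate carries an a-priori direction
of effect (negative for roads, residential and industrial area, temples,
cemeteries, NOx and relative humidity; positive for forest, crops, NDVI,
temperature and altitude), and a candidate can only enter if its sign agrees
with that prior.

All coordinates are planar metres in one projected CRS; the package performs
no geodesic computation. Real-data users must project beforehand.

## Buffer extraction geometry

The extraction primitives are deliberately specified to the millimetre so that
they can be tested against independent oracles:

* **Disk boundary is closed**: a feature at distance exactly $r$ counts. This
  makes results deterministic at ladder boundaries.
* **Point counts** are exact distance comparisons.
* **Line lengths** use exact segment–circle clipping: the entry/exit
  parameters of each segment solve a quadratic, so the result is exact up to
  floating point. Degenerate zero-length segments contribute 0.
* **Polygon areas** intersect the *union* of the layer's polygons (so
  overlapping polygons are never double-counted) with the disk represented as
  a regular inscribed 256-gon. The union–intersection area is computed
  exactly by a slab scanline in compiled code: between consecutive critical
  $y$ values (vertices and pairwise edge crossings) the cross-section's
  structure is constant and its length linear in $y$, so midpoint evaluation
  integrates each slab exactly. The only approximation is the 256-gon itself,
  whose area deficit is $1 - \frac{n}{2\pi}\sin\frac{2\pi}{n} \approx 1.0
  \times 10^{-4}$ of the disk — the package's documented accuracy bound for
  polygon buffers. Rings must be simple; self-intersecting input is rejected
  at layer construction with the offending polygon index.
* **Raster means** average the cells whose *centres* fall in the disk (the
  common zonal-statistics default; area weighting is out of scope). A buffer
  with no qualifying cell centre is missing; a buffer wholly outside the
  raster extent additionally warns.

The default radius ladder is
`r paste(buffer_radii(), collapse = ", ")` m — every radius that
buffer-based ozone LUR models in this range actually select — with
`buffer_radii(dense = TRUE)` providing the full 25 m step grid (200 radii)
for users who want it. The dense grid multiplies the candidate count roughly
twelvefold without adding support at new scales, so the coarse ladder is the
default.

## The selection algorithm

`forward_select()` implements the supervised stepwise procedure:

1. Seed with the candidate of highest univariate $R^2$ whose slope has the
   expected sign (unconstrained candidates are always eligible). If no
   candidate is eligible the intercept-only model is returned.
2. Each round, every remaining candidate is added alone to the current model.
   A candidate is *admissible* iff
   (i) its own two-sided $t$-test p-value is below `p_enter` (default 0.1);
   (ii) its own coefficient sign matches its prior;
   (iii) no previously entered constrained coefficient flips sign;
   (iv) every VIF of the augmented model is below `vif_max` (default 3),
   with $\mathrm{VIF}_j = 1/(1-R^2_j)$ from regressing predictor $j$ on the
   other model predictors.
3. Among admissible candidates, the one with the largest adjusted-$R^2$ gain
   enters, provided the gain exceeds `min_adj_r2_gain`; ties break by smaller
   p-value, then lexicographic name, so selection is fully deterministic.
4. Entered terms are never removed, even if their p-value later rises above
   the entry gate — mirroring how published supervised-LUR tables retain
   late-stage terms whose significance eroded as colinear terms entered.
5. Selection stops when no candidate is admissible (or `max_terms` is hit).

Each term records its **incremental $R^2$** — the gain in model $R^2$ at the
round it entered. These increments telescope: they are non-negative and sum
exactly to the final model $R^2$, which the test-suite asserts to $10^{-9}$.

**Why `min_adj_r2_gain = 0.01` by default.** With ~150–190 candidate columns,
the smallest p-value among remaining candidates is below 0.1 essentially
every round by chance alone ($1 - 0.9^{140} \approx 1$), so a pure
p/VIF-gated forward selection only stops when the sign and collinearity gates
happen to block everything, and accumulates many spurious terms on the way.
Requiring each entrant to add at least 1% adjusted $R^2$ is the conventional
guard in supervised LUR model building and is the package default; setting it
to 0 restores the pure p/VIF-gated procedure. p-values are classical OLS
t-tests with no multiple-testing correction, as is conventional in this
literature.

**Response transform.** The default fits the response in its native units
(ppb). A `log10` switch is provided because published coefficient tables in
this area are sometimes only dimensionally consistent with a log-transformed
response; predictions are back-transformed automatically.

**Degenerate inputs.** A constant response is fitted with the convention
$R^2 = 0$ and zero slopes. Constant design columns are flagged in the column
metadata and excluded from candidacy. Perfectly collinear VIFs are reported
as `Inf` rather than raising; a rank-deficient final fit raises an error
naming the dependent columns.

## Validation conventions

* **Fold unit is the monitoring site**, never the row: all periods of a site
  are held out together (`make_site_folds()`, uniform partition with fold
  sizes differing by at most one, reproducible from a seed). Row-wise folds
  would leak a site's own temporally-averaged surroundings into its own
  validation.
* **Per-fold re-selection is the default** (`mode = "reselect"`): the whole
  forward selection is re-run on each training 90%, so the reported CV skill
  includes variable-selection uncertainty. `mode = "refit"` keeps a given
  term structure and re-estimates only its coefficients — useful for
  validating a published term set.
* **Two $R^2$ conventions are reported**: `cv_r2`, the squared Pearson
  correlation of pooled out-of-fold predictions against observations (the
  convention most LUR papers use), and `cv_r2_sse` $= 1 - \mathrm{SSE} /
  \mathrm{SST}$ on the same pooled pairs. Predictions with zero variance
  (e.g. every fold returned an intercept-only model) score 0 by convention.
* **Temporal external validation** (`external_validate()`) trains on all
  periods before a holdout year and evaluates on that year only.

A subtlety worth stating plainly: *exact* noiseless recovery — CV $R^2 = 1$
to $10^{-9}$ on a noise-free planted scene — is a property of the validation
algebra, not of the greedy selector. Even with zero noise, greedy forward
selection over a collinear radius ladder can prefer a neighbouring radius of
a true term (a single column may beat the true one at reducing the *combined*
residual), after which the true column is VIF-blocked. The package therefore
verifies noiseless exactness in refit mode on the planted term set (via
`fit_lur()`), and measures ladder identifiability separately with the
recovery experiment below.

## The synthetic scene generator

`generate_scene()` emulates the data landscape of an island-wide ozone
monitoring study on a 50 km × 50 km planar region with 73 stations in six
classes (general/traffic/industrial/national-park/background/other in
56/5/4/2/4/2 proportions), eight monitoring years, and:

* temple and cemetery landmark layers as homogeneous Poisson point processes
  (0.31 and 0.08 points/km²; the temple intensity is the national
  registered-temple density),
* road and main-road networks as random segments, land-use rectangles for
  residential, mixed-residential, industrial, forest, crop and water classes,
* power-plant and incinerator point sources used in nearest-distance mode,
* an NDVI-like raster on 250 m cells from a smooth random field (a sum of
  random low-frequency cosines with ~5 km correlation length),
* station-year covariates: NOx tied to the 1000 m road-length around each
  station plus year and station noise — so NOx carries the titration
  structure (negative association with ozone) at the level of correlation;
  temperature and relative humidity as per-year station draws; altitude from
  a smooth terrain field.

The response is planted as a linear combination of *buffer-extracted* design
columns — generation runs the same extraction engine as analysis, so the
generator itself exercises the geometry code — plus Gaussian noise. The
default true model has six terms (NOx, forest@500, temple@500,
residential@1000, cemetery@3000, altitude) whose signs follow the prior
catalog and whose relative signal-variance shares (0.60, 0.10, 0.08, 0.08,
0.07, 0.07) mimic the steep leading-term profile typical of published ozone
LUR tables. Coefficients are scaled against the realized design so the
response mean and standard deviation land near 27.96 and 3.98 ppb, and the
noise is calibrated as
$\sigma^2 = \mathrm{var(signal)} \times (1 - R^2_\ast) / R^2_\ast$
with target population $R^2_\ast = 0.75$ (an explicit `noise_sd`, including
0, overrides the calibration).

Scenes are pure functions of `(config, seed)`; serialization to
GeoJSON/ASCII-grid/CSV/JSON is byte-deterministic. Replicate seeds in
`recovery_experiment()` derive from the base seed by a simple counter
(`seed + replicate`), so experiments are reproducible and parallelizable.

**What the generator does not emulate**: atmospheric chemistry or dispersion
(the NOx–ozone link is correlational only), island-shaped geography or
coastal gradients, survey-vintage changes in land-use layers, monthly
dynamics, spatially autocorrelated residuals, and measurement error in the
predictors. Passing recovery tests on these scenes therefore demonstrates
that the pipeline is algebraically and algorithmically sound under its own
assumptions — not that a real ozone surface is identified this well.

## What the experiments show — and their known limits

`recovery_experiment()` scores the selected model against the planted truth.
At the default study scale (73 stations × 8 years, ~180 candidate columns,
population $R^2$ 0.75, 20 replicates) false positives average well under 3
and recovered coefficients are within a few percent of truth, but the
*exact-column* true-positive rate sits near 0.75–0.82 depending on the seed:
essentially every miss is a same-layer adjacent-radius substitution
(forest@750 for forest@500, residential@750 for residential@1000). Adjacent
radii of one layer are nearly collinear — forest patches of 1–6 km make the
250–750 m forest buffers correlate above 0.95 — so the exact radius is only
weakly identified, and once a neighbour enters, the true column is VIF-blocked.
The radius-blind recovery rate (`recovery_rate_layer`) is 1.0. This is a
statistical property of buffer ladders, not an implementation artefact, and
it is the reason published LUR tables should be read as identifying *layers
and scales approximately*, not exact radii.

Problem sizes used by the test-suite and the acceptance script are the
package's own choices: oracle comparisons run 100 random configurations per
primitive (with a $10^6$-point Monte-Carlo oracle for polygon areas and a
0.01 m dense-sampling oracle for line clipping); module tests use a reduced
20 km / 30-station scene with the same generative processes; the recovery
and cross-validation experiments run 20 replicates at the full default
scale.

## Worked example

```{r example, eval = FALSE}
cfg   <- scene_config(seed = 42)
scene <- generate_scene(cfg)
meas  <- generate_measurements(scene)

model <- forward_select(meas$design, meas$response)
model

folds <- make_site_folds(scene$stations, k = 10, seed = 42)
cross_validate(meas$design, meas$response, folds)

external_validate(meas$design, meas$response, holdout_year = 2013)

# exposure surface on a 20 x 20 grid, with IDW rasters for the covariates
grid <- grid_spec(c(0, 0), cellsize = 2500, ncol = 20, nrow = 20)
ann  <- meas$design[meas$design$year == 2013, ]
covs <- lapply(c(nox = "nox", altitude = "altitude"), function(cn) {
  v <- tapply(ann[[cn]], ann$station_id, mean)[scene$stations$station_id]
  idw_raster(scene$stations, as.numeric(v), grid)
})
surface <- predict_surface(model, scene$layers, covs, grid)
```

Buffer and distance terms are extracted at each grid-cell centre by the same
engine that built the training design; station-measured covariates have no
natural value at arbitrary cells, so the package requires covariate rasters
and ships `idw_raster()` (inverse-distance weighting, power 2, over all
stations) as a transparent, clearly-labelled modelling choice for building
them. Margin cells whose buffers extend beyond the supplied layers are still
computed — layers are treated as complete — and `edge_mask = TRUE` flags
cells within the maximum model radius of the grid edge.

## Data formats

Stations and period tables are CSV (UTF-8, ISO-8601 dates). Vector layers are
GeoJSON FeatureCollections in planar metres, with the layer's sign prior,
mode and radii stored in the collection properties. Rasters are ESRI ASCII
grids. Models serialize to a versioned JSON schema and a summary-table CSV;
validation reports to JSON. All serializations are byte-stable for fixed
inputs, which the determinism tests assert.

Daily measurement tables aggregate to annual or monthly means with
`aggregate_to_periods()`; a row is kept only if the fraction of days with a
valid ozone value reaches the completeness threshold (default 0.75, the
usual regulatory convention — the threshold is configurable because data
providers differ). Mixing-ratio/mass-concentration conversion uses
$c_{\mu g/m^3} = c_{ppb} \times M / V_m$ with ozone defaults $M = 48.00$
g/mol and $V_m = 24.45$ L/mol (25 °C, 1 atm), both overridable.

## Known limitations

* Exact-radius identifiability is weak by construction (see above); selection
  results should be interpreted at the layer/scale level.
* The greedy selector has no backward pass; early entrants whose p-values
  erode are retained by design.
* Squared-Pearson validation $R^2$ is insensitive to calibration drift
  (slope/intercept bias); `cv_r2_sse` is reported alongside for that reason.
* IDW covariate rasters are a modelling choice, not geostatistics; kriging
  and spatially blocked CV are out of scope.
* Monthly aggregation is supported, but model fitting targets annual means;
  buffer layers are treated as time-constant.
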