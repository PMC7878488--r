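---
title: "Carrying-capacity accounting with wild ungulate coexistence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrying-capacity accounting with wild ungulate coexistence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangecap)
```

rangecap closes a sheep-unit ledger for grasslands shared by livestock and
wild ungulates. This vignette explains the models behind each stage, the
parameters that matter and their defaults, what the synthetic county does
and does not emulate, and the numerical choices and limitations a user
should know about before trusting the output.

## The accounting chain

Everything is expressed in sheep units (SU): one standard sheep's daily
forage intake, `I = 4.0` kg/day here. For a land parcel of area $S$ km²:

$$C_{tp} = \frac{Y \cdot E \cdot U}{I \cdot T}, \qquad
  C_w = \sum_i D_i S_i K_i, \qquad
  C_t = C_{tp} \cdot S - C_w, \qquad
  \mathrm{RCC} = C_t - \mathrm{actual}.$$

* $Y$ — grass yield per unit area, from NDVI (below).
* $E = 0.85$ — edible forage ratio: the share of standing yield livestock
  can eat. $U = 0.65$ — grazing utilization rate: the share of edible
  forage that can be removed while sustaining production. Both are
  dimensionless fractions in (0, 1], standard values for alpine steppe and
  meadow.
* $T = 365$ grazing days/year.
* $D_i$ — parcel mean density of wild species $i$ (animals/km²);
  $K_i$ — its sheep-unit rate (kiang 6, Tibetan gazelle 0.3, from body-mass
  ratios).

The per-parcel identities $C_t + C_w = C_{tp}\cdot S$ and
$\mathrm{RCC} + \mathrm{actual} = C_t$ are enforced exactly (asserted to
$10^{-9}$ SU in the tests), and every county total is the exact sum over
parcels because parcels tile the county and cells are assigned uniquely by
cell-centre containment. A parcel is *overloaded* iff $\mathrm{RCC} < 0$;
$\mathrm{RCC} = 0$ counts as exactly at capacity. Negative $C_t$ (wildlife
demand exceeding usable forage) is permitted and flagged, not clipped.

Livestock head counts convert at sheep = 1, cattle = 4.5, horse = 6
SU/head. These per-head rates follow common Chinese rangeland practice;
published county studies typically report only the aggregate SU figure, so
the rates are config-exposed and a `sheep_units` passthrough column is
accepted where the aggregate is known directly (`actual_load()`).

## Forage yield from NDVI

Acquisition layers are combined by the maximal-value composite (per-cell
maximum, the standard device against cloud and atmospheric low bias;
nodata only where all layers are nodata), then converted by the published
alpine-grassland regression

$$Y = -47.021 + 440.21 \cdot \mathrm{NDVI}.$$

Below NDVI $\approx 0.107$ the line goes negative; yields are clamped to
zero by default and the clamp count is logged. The regression's source
does not state its output unit, so the unit is explicit configuration
(`yield_params(unit =)`, default `kg/ha`) carried through all totals
rather than an assumption baked into the code; the synthetic county uses
`g/m2` (numerically identical to t/km²), under which a county mean
composite NDVI of ~0.22 yields county totals near 1.3 million tons — the
magnitude reported for the study system. County-scale checks against
published aggregates feed the published total yield directly
(`theoretical_capacity_total()`), so they do not depend on the unit guess.

## Wildlife density surfaces

**Strip-transect densities.** Each survey line yields
$\mathrm{SAD} = \mathrm{count} / (2 w L)$ animals/km², located at the line
midpoint. The effective half-width $w$ is the single tunable of this
estimator; it must match the strip under which counts were collected
(the pipeline config defaults both to 1.5 km). The standalone
`estimate_sad()` default is the conventional 0.5 km. No distance-sampling
detection function is fitted — field campaigns of this kind report raw
discovery rates, and the half-width absorbs the effective detection width.
Seasonal revisits are merged by the arithmetic mean at matched locations
(`max` and passthrough are available); the mean is the natural choice when
seasons are replicate observations of one annual surface.

**Ordinary kriging.** The Matheron estimator bins squared differences by
separation (bin width = the 5 km cell size, about the mean
nearest-neighbour spacing of the default survey; maximum lag 80 km), a
spherical/exponential/gaussian model is fitted by weighted least squares
(weights $N_k/h_k^2$, bounded L-BFGS-B from four starts), and predictions
use the 16 nearest points per cell through the ordinary-kriging system in
covariance form ($C = \mathrm{sill} - \gamma$) with a Lagrange multiplier
enforcing $\sum \lambda = 1$. The covariance and variogram forms give
identical weights (asserted against a dense solve in the tests). Negative
predictions are clamped to zero — densities cannot be negative — with the
count logged. A singular neighbourhood system gets one retry with a tiny
diagonal jitter. Pure-nugget data are flagged `range_identifiable = FALSE`
when the structured component is under 10% of the sill or barely improves
on the best flat fit. Global (all-point) kriging is available via
`neighborhood = Inf` and is sensible up to a few hundred points.

**Habitat range mask.** A presence-only maximum-entropy model over all
county cells as background: features are standardized linear + quadratic
terms per covariate (circular aspect enters as sin/cos), and the Gibbs
distribution $p(\mathrm{cell}) \propto \exp(\beta^\top f)$ is fitted by
proximal gradient descent with backtracking, so the L1-penalised objective
is non-increasing every iteration and $\sum p = 1$ holds throughout. The
penalty is $\beta/\sqrt{m}$ per unit coefficient ($m$ = presence cells,
$\beta = 0.5$ default): presence feature means carry $O(1/\sqrt m)$
sampling error, and holding the penalty proportional to that noise keeps
one global weight meaningful at any survey size. At $\beta = 0$ the fit
matches the presence feature means exactly — the defining moment condition
— which the tests verify against a coefficient-grid oracle. Hinge/product
features of full Maxent are deliberately omitted: the model's only job
here is a range mask, and linear + quadratic terms keep the problem
convex and the optimum interpretable.

Suitability ($r/(1+r)$ with $r$ the relative occurrence rate; 0.5 under
the uniform model) is thresholded at the 10th percentile of suitability at
presence cells (inverse-ECDF quantile, ties inclusive) — a common Maxent
convention that keeps at least 90% of presences inside the range. The
kriged density is then *clipped* to the mask without renormalisation:
"combining" a range map with a density surface is interpreted as zeroing
density outside the range, and population totals are therefore computed
after masking, with the removed mass logged.

## The synthetic county

The generator exists so that every downstream stage can be tested against
known truths; all of it is deterministic in (config, seed).

* **Parcels** are a recursive random binary split of the extent into
  grid-aligned rectangles (split the largest remaining rectangle along its
  longer axis at a random interior grid line). Any exact tiling serves the
  accounting; rectangles aligned to the 5-km grid make cell-centre zonal
  assignment partition-exact, so conservation checks hold to machine
  precision. The boundaries are abstractions of grazing-management units,
  not realistic cadastral shapes.
* **Covariates**: elevation is a smooth Gaussian random field (random
  Fourier features, squared-exponential covariance) around 4,500 m; slope
  and aspect are its finite-difference gradient; temperature follows a
  lapse rate plus an independent anomaly field; precipitation is a smooth
  field around 304 mm. These have the right roughness and
  cross-dependence structure for testing, not Tibetan-Plateau realism.
* **Species truths**: suitability truth is a known logistic function of
  the standardized covariates thresholded at probability 0.5; latent
  density is a log-Gaussian field restricted to suitable cells and scaled
  so density × cell area integrates to the configured total.
* **Surveys**: lines of 10 km are placed uniformly (orientation uniform,
  midpoint uniform over the sub-extent keeping the line inside) and
  revisited each of 2 seasons; counts are Poisson with mean = line-mean
  density × 2wL × detection. Defaults (250 lines/season, w = 1.5 km,
  detection 1) make the expected discovery rates equal the configured
  county totals divided by county area times 2w. The default totals
  (11,349 kiangs, 4,181 gazelles) are chosen so those rates are 1.33 and
  0.49 animals/km/season — the published survey rates. The published
  *model-based* population estimates (11,397 and 1,545) are mutually
  inconsistent with those rates under any single strip geometry, because
  they come from a different stage of the original workflow; the generator
  prioritises the raw survey rates, which are the quantities a survey
  design controls.
* **Livestock**: parcel sheep-unit allocations proportional to area times
  a lognormal factor (sd 0.4); cattle and horse heads are rounded from
  their SU shares and the sheep class absorbs the residual, so the county
  total is within n_parcels/2 SU of the configured 338,159.
* **NDVI**: a smooth latent greenness field observed on 4 dates with
  multiplicative cloud dips on ~30% of cells per date, so the maximal
  composite nearly recovers the latent field.

What passing tests on this county show: the estimators recover known
truths under their own assumptions (Poisson strip counts, smooth latent
fields, covariate-driven ranges, exact tilings). What they do not show:
robustness to detection heterogeneity, observer effects, non-stationary
or anisotropic spatial structure, misaligned real-world rasters, or
boundary parcels of irregular shape.

## Numerical choices and degenerate inputs

* Planar km coordinates throughout; no geodesy. Cells are registered at
  centres, row-major from the north-west corner; cell area is exactly
  25 km².
* Rasters travel as plain-text ESRI ASCII grids (nodata −9999), parcels
  as GeoJSON, tables as CSV — all hand-inspectable and diff-able.
* Kriging with one data point returns that value everywhere; coincident
  points are rejected in the empirical variogram; a constant field fits a
  zero variogram and cross-validates with zero error.
* A constant covariate is dropped from the feature space with a warning;
  an empty range mask is a warning, not an error; a species never observed
  gets an all-zero range and surface rather than a failed fit.
* The maxent optimizer errors with its objective trace attached if the
  iteration cap is hit (the cap matters only for the unpenalised boundary
  case where the optimum is at infinity).
* Tiny negative kriging variances (> −10⁻⁹, floating-point round-off) are
  set to zero; anything more negative is a genuine error and surfaces.

## Known limitations

* Clipping the kriged surface by the range mask without renormalisation
  systematically loses the mass that interpolation smears across the range
  boundary: on the default county this is a 9–11% negative bias in
  recovered populations, on top of ~8% (1 s.d.) survey sampling noise.
  Users who need unbiased abundance totals should treat the masked
  integral as a lower bound, or renormalise explicitly — the removed mass
  is logged per species for exactly that purpose.
* The strip half-width is a convention, not an estimate; absolute
  densities scale inversely with it. Discovery rates and relative spatial
  patterns are unaffected.
* The semivariogram is isotropic and stationary; sharp range edges in the
  truth are necessarily smoothed at the variogram's scale.
* Problem sizes in the test-suite pipeline runs (a 32 × 32 grid of 5-km
  cells, 500 transect surveys, 27 parcels) are the package's default study
  conditions; they keep a full run around one second on one core.
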