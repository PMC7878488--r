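# rangecap

Rangeland livestock carrying capacity with wild-ungulate coexistence, for
alpine grasslands where domestic herds share forage with wild grazers such
as the kiang (*Equus kiang*) and the Tibetan gazelle (*Procapra
picticaudata*). The package is aimed at spatial ecologists and rangeland
managers who need a per-parcel answer to "how much livestock can this
grassland still carry once the wild herbivores have eaten?"

## The accounting model

All quantities are expressed in **sheep units (SU)** — one standard sheep's
daily intake, here `I = 4.0` kg of forage per day. The chain, per land
parcel of area `S` (km²):

1. **Forage yield.** Per-cell grass yield from a maximal-value NDVI
   composite, `Y = -47.021 + 440.21 · NDVI` (negative values clamped to 0).
2. **Theoretical carrying capacity** per unit area:
   `C_tp = (Y · E · U) / (I · T)` with edible forage ratio `E = 0.85`,
   grazing utilization rate `U = 0.65`, and `T = 365` grazing days.
3. **Wildlife offset.** `C_w = Σ_i D_i · S_i · K_i` over wild species `i`
   with parcel mean density `D_i` (animals/km²) and sheep-unit rates
   `K_kiang = 6`, `K_gazelle = 0.3`.
4. **Ecological carrying capacity.** `C_t = C_tp · S − C_w`.
5. **Residual carrying capacity.** `RCC = C_t − actual livestock load`;
   a parcel with `RCC < 0` is overloaded.

The wildlife densities come from line-transect surveys: per-line species
abundance density (`SAD = count / (2 · halfwidth · length)`) is
interpolated onto a 5 × 5 km grid by ordinary kriging (Matheron empirical
semivariogram, bounded WLS model fit, moving-neighborhood solve), then
clipped to a binary range mask from a presence-only maximum-entropy
habitat model (linear + quadratic features, L1-regularised Gibbs
distribution, 10th-percentile presence threshold).

Because the original field, household-survey and satellite inputs are not
public, the package ships a **synthetic county generator** (`make_county()`,
`make_truth()`, `simulate_surveys()`, `simulate_livestock()`,
`simulate_ndvi()`) that reproduces the statistical structure of the study
system — 27 parcels tiling a 160 × 160 km county, two species with known
latent density surfaces, seasonal transects calibrated to mean discovery
rates of 1.33 and 0.49 animals/km/season, and a livestock table with a
73/24/3% cattle/sheep/horse sheep-unit mix — so every stage is testable
against known truths.

## Worked example

County-scale ledger from published aggregates (total annual grass yield
1,293,500 t; 11,397 kiangs and 1,545 Tibetan gazelles; 338,159 SU of
livestock):

```r
library(rangecap)
led <- county_ledger(grass_yield_t = 1293500,
                     populations = c(kiang = 11397, gazelle = 1545),
                     actual_su = 338159)
str(led)
#> List of 4
#>  $ C_tp: num 489492
#>  $ C_w : num 68846
#>  $ C_t : num 420647
#>  $ RCC : num 82488
```

So the grass yield supports ~489,492 SU; the wild herbivores claim
~68,846 SU; ~420,647 SU remain for livestock, of which ~82,488 SU are
still unused at the current stocking level.

Full synthetic-county pipeline (about one second):

```r
cfg <- default_config(seed = 1, output_dir = "rangecap_run")
acc <- run_all(cfg)        # per-parcel ledger data.frame
read.csv("rangecap_run/county_summary.csv")
#>                quantity        value
#> 1      population_kiang   10262.0298
#> 2    population_gazelle    3463.2717
#> 3         yield_total_t 1170847.8144
#> 4                  C_tp  443077.6832
#> 5                   C_w   62611.1602
#> 6                   C_t  380466.5230
#> 7             actual_su  338160.0000
#> 8                   RCC   42306.5230
#> 9  n_overloaded_parcels      10.0000
```

Here the masked kriged surfaces estimate ~10,262 kiangs and ~3,463
gazelles against latent truths of 11,349 and 4,181; ten of the 27 parcels
are overloaded. The run directory also holds every intermediate raster,
the fitted variograms, a per-parcel `parcel_accounts.csv`, the parcels
with RCC joined back on (`parcels_rcc.geojson`) and a plain-text
`report.txt` with full provenance.

The same stages are available from a shell via the thin CLI in
`inst/cli/rangecap`:

```sh
rangecap run --seed=1 --out=rangecap_run
rangecap account --config=my_config.yaml --out=rangecap_run
```

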