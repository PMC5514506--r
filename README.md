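# granusim

Individual-based simulation of *de novo* anaerobic sludge granulation.

In up-flow anaerobic sludge blanket (UASB) reactors, dispersed microbes
self-organise into dense spherical granules that carry the whole
digestion chain. `granusim` models this process from first principles
for users who study anaerobic digestion or multicellular
self-organisation: every cell is a spherical agent — **acidogens**
fermenting glucose to acetate, **methanogens** converting acetate to
methane — growing by Monod kinetics on reaction–diffusion solute
fields, dividing, starving into an inert dead core, and mechanically
packed by shoving, adhesion and agitation.

The model couples, per 1 h step:

* pseudo-steady solute fields on a 2-D grid,
  `0 = ∇·(B(x,y) D ∇S) + r(S)`, with biofilm diffusivity
  `B = γ = 0.3` inside biomass; glucose held at the bulk value `SBulk`
  on all edges, acetate accumulating under a closed boundary, volatile
  methane absorbed at the far boundary;
* growth `μ_a = μ̂_a · S_g/(K_sg+S_g) · K_i/(K_i+S_a)` (acidogens,
  product-inhibited) and `μ_m = μ̂_m · S_a/(K_sa+S_a)` (methanogens),
  with stoichiometric secretion (0.82 g acetate/g glucose,
  0.26 g CH₄/g acetate);
* a 48 h starvation death switch producing inert biomass, division at
  a 3 µm radius, and iterative overlap relaxation ("shoving").

Emergent results: a ~0.5 mm granule in ~650 simulated hours with the
experimentally observed stratification (dead core, methanogen shell,
acidogen rim), reactor-scale aggregation of a dispersed inoculum, and
methane-yield response surfaces over feed strength and inoculum
composition.

## Worked example

A small granule-maturation run (coarse 8 µm grid; ~8 s):

```r
library(granusim)

proto <- default_protocol(grid_resolution = 64)   # 508 µm domain, SBulk 0.175 g/L
run   <- run_simulation(proto, seed = 1, duration = 100)

glance(run)
#> # A tibble: 1 × 8
#>    time acidogens methanogens  dead diameter_mm dead_core_radius_um   ch4_ml activity_ml_per_g
#>   <dbl>     <int>       <int> <int>       <dbl>               <dbl>    <dbl>             <dbl>
#> 1   100       195         103     0      0.0903                   0 4.21e-6              683.
```

After 100 h the seed agglomerate has grown into a 90 µm cluster: the
acidogens (fast, glucose-fed) have nearly doubled, the methanogens are
just leaving their acetate-starved lag phase, and methane production
is under way — `activity_ml_per_g` is the cumulative CH₄ gas volume
per gram of biomass. Running the same protocol to 650 h yields a
~0.6 mm granule with a ~200 µm inert core, whose radial census
(`radial_profile()`, `radial_means()`) shows the
dead < methanogen < acidogen ordering of mean radial positions.

Longer runs chain into the analysis and plotting layer:

```r
run650 <- run_simulation(proto, seed = 1)          # 650 h, ~2–3 min
granule_metrics(run650)                            # centroid, diameter, dead core
radial_profile(run650, n_bins = 5) |> autoplot()   # quarter-wise stratification
specific_methanogenic_activity(run650)             # CH4 volume per g biomass
tidy(run650)                                       # full per-step summary series
autoplot(run650$state)                             # draw the granule
```

A methane-yield scan over feed strength and inoculum composition:

```r
spec <- scan_spec(glucose_values = c(0.1, 0.25, 0.4),
                  varied_species = "methanogen",
                  varied_counts = c(10, 100, 900),
                  fixed_count = 100, seeds = 1:3, duration = 300)
res <- run_scan(spec, default_protocol(grid_resolution = 64))
best_cell(res)
autoplot(res)   # heatmap, ml CH4 / g biomass
```

Protocol files are a small XML dialect (see
`inst/extdata/granule_default.xml`); `load_protocol()` /
`write_protocol()` round-trip them, and `inst/cli/granusim.R` wraps
`run` / `analyze` / `scan` for shell use:

```sh
Rscript inst/cli/granusim.R run inst/extdata/granule_default.xml \
        --out out/ --seed 7 --duration 650
```

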