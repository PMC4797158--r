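# riparia

Movement ecology and habitat suitability of riparian thicket birds.

East African rivers are lined by dense thickets that shelter a
disproportionate share of endemic birds, but most of the original
vegetation has been cleared for agriculture or replaced by the invasive
shrub *Lantana camara*. Whether this novel ecosystem works as surrogate
habitat is a practical conservation question: it determines if the remnant
*L. camara* bands along rivers are worth protecting. `riparia` implements,
as a tested and reusable pipeline, the analysis chain used to answer it
with small-scale radio telemetry:

- **Telemetry**: triangulation of paired observer compass bearings into
  fixes (forward-ray intersection), with the 1000 m observer-distance
  filter for unreliable long-range fixes.
- **Home ranges**: 95% minimum convex polygons (hull of the 95% of fixes
  nearest the centroid) and kernel utilization distributions with the
  normal-reference bandwidth `href = sqrt((var(x)+var(y))/2) · n^(-1/6)`,
  contoured at the 95/75/50% use levels, plus area-accumulation curves.
- **Habitat preference**: the Jacobs selectivity index
  `D = (r − p)/(r + p − 2rp)` comparing the habitat composition of each
  bird's K75 core area (`r`) with availability (`p`), tested with the exact
  sign test; per-habitat movement rates in m·10 min⁻¹.
- **Site fidelity**: a bootstrap random-walk null model — 1000 paths
  rebuilt from resampled observed step lengths and turning angles; fidelity
  is flagged when the observed range falls below the null's 95% CI.
- **Habitat suitability**: a maximum-entropy presence–background model
  (L1-regularized Gibbs density over background cells with linear,
  quadratic and product features) in a chained design: a distance-to-river
  pre-model binarized at the 10-percentile training-omission threshold
  masks the background; a spectral *L. camara* sub-model fitted on seven
  red-edge vegetation indices (NDVI, REGNDVI, GNDVI, NDRE, GCM, GRM,
  RENDVI) becomes a predictor of the final per-species models, which are
  evaluated over ten replicate 70/30 presence splits by rank-based AUC.
- **Synthetic data**: seeded generators for river-centred landscape
  mosaics, class-conditional 5-band reflectance rasters, habitat-biased
  correlated-random-walk bird tracks (step-selection rule) and noisy
  observer bearings, so the whole pipeline runs and is testable end to end
  without field data.

## Worked example

```r
library(riparia)

## reference cohort of 14 radio-tracked birds (published per-individual
## home-range sizes, bundled as a worked example)
hr <- bird_home_ranges()
round(mean(hr$mcp95_ha), 1)   # 52.8 ha mean MCP95
round(mean(hr$k95_ha), 1)     # 61.8 ha mean K95
a <- one_way_anova(split(hr$mcp95_ha, hr$species), transform = "none")
sprintf("F(%d,%d) = %.2f, p = %.2f", a$df1, a$df2, a$F, a$p_value)
# "F(3,10) = 3.12, p = 0.07"  -> no home-range size difference among species

## a fully synthetic bird, end to end
map <- generate_landscape(landscape_spec(seed = 1))
tr  <- generate_track(map, movement_spec(n_fixes = 400, seed = 2), "BT1")

mcp(tr)
# MCP95 home range (BT1) : 60.92 ha
ud <- kernel_ud(tr)
ud_contour(ud, 0.75, "BT1")
# K75 home range (BT1) : 35.71 ha        (the core area)

## habitat preference of the core area: strong L. camara preference,
## avoidance of the agricultural matrix
k75  <- ud_contour(ud, 0.75, "BT1")
comp <- landscape_composition(map)
p    <- setNames(comp$pct / 100, comp$class)
r    <- habitat_fractions(k75, map)
round(jacobs_index(r, p[names(r)]), 2)
# indigenous  mixed  lantana  crops_low  crops_high  settlement
#       0.69  -1.00     0.72       0.29       -0.67       -1.00

## site fidelity against the random-walk null
rwm_simulate(tr, n_sims = 1000, seed = 3, estimators = "MCP95")$MCP95
# observed 60.92 ha; null 95% CI [750.96, 3708.15] ha; site fidelity: TRUE
```

The Jacobs values say the bird's core area holds *L. camara* (D = 0.72,
preference) far beyond its availability while tall crops (−0.67) and
settlements (−1.00) are avoided; the null model says a bird moving with the
same step lengths but no site fidelity would cover an order of magnitude
more ground.

`run_pipeline(pipeline_config(...))` orchestrates all stages from input
files (bearings/fixes CSV, land-cover GeoJSON, 5-band raster TIFF) to a
manifest of output artifacts; `inst/scripts/riparia-pipeline.R` is a thin
command-line wrapper around it.

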