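# forestbirdiv

Which attributes of a managed plantation forest matter most for breeding
bird diversity — stand age class, tree species composition, or the fine
structural detail that airborne LiDAR can measure? `forestbirdiv`
implements the full analysis chain for answering that question at the
scale of forest management compartments, together with a seeded synthetic
landscape generator so the whole chain is testable end to end without any
field data.

The pipeline:

1. **LiDAR structure** — canopy height models (per-cell maximum, 0.5 m,
   mean-aggregated to 2/5/10 m) and MacArthur–Horn plant-area density
   profiles (10 m columns, 1 m bins), summarised into six per-compartment
   metrics: top canopy height, gap fraction, horizontal heterogeneity
   (Moran's *I*, rook contiguity), vertical evenness (Pielou's *J*), shrub
   density (PAD over 1–5 m) and canopy density (PAD over the top third of
   the canopy).
2. **Community assembly** — two-visit bird surveys collapsed to maximum
   counts, compartments grouped by management type × age class (area
   ≥ 0.05 ha, ≥ 10 members per group), abundances corrected by
   species-specific detectability constants, covariates averaged per group
   with log total area as a confounder control.
3. **Diversity** — species richness, Shannon diversity, and functional
   richness/evenness/divergence/dispersion (FRic/FEve/FDiv/FDis) in a
   Gower/PCoA trait space, with Shapiro–Wilk checks and Box–Cox
   normalisation (profile-likelihood lambda).
4. **Variable importance** — hierarchical partitioning of OLS *R*² over
   all predictor subsets (≤ 9 variables): for each variable *j*,

   *I*ⱼ = (1/k) Σₕ mean over subsets S of size h without j of
   [R²(S ∪ {j}) − R²(S)],   *J*ⱼ = R²({j}) − *I*ⱼ,

   with Σ *I*ⱼ = R²(full) exactly. The same decomposition picks the best
   raster resolution per structural variable (highest percentage of
   independent effects).
5. **Final models** — collinearity screening at |0.7| (Pearson /
   correlation ratio / Cramér's V), exhaustive selection of the edge-free
   subset with the greatest total independent effects, OLS with stated
   baselines (age "Mixed", management "Conifer"), type-2 ANOVA and
   residual diagnostics.

## Worked example

```r
library(forestbirdiv)

cfg <- pipeline_config(n_compartments = 800, seed = 101)
res <- run_forest_bird_analysis(cfg)
summary(res)
```

```
Groups analysed: 22 (input compartments: 800)

Leading non-area variable by independent effects:
   metric          variable percent_independent
 richness management_simple                22.2
  shannon        age_simple                43.2
     fric management_simple                23.3
     feve        age_simple                22.8
     fdiv        age_simple                39.4
     fdis        age_simple                41.9

Final model R2:
richness  shannon     fric     feve     fdiv     fdis 
   0.939    0.904    0.886    0.746    0.981    0.978
```

The landscape of 800 compartments collapses to the groups analysed
(management × age-class combinations with at least ten members). For each
of the six diversity metrics the summary reports the leading non-area
variable by independent effects — on synthetic landscapes, where stand age
class is simulated as the dominant driver of bird composition, age class
should head most of these rankings — and the final linear model *R*².
`variable_ranking(res)` gives the full per-metric ordering,
`res$models$richness` the fitted model objects (with `summary()`,
`coef()`, `predict()`, `residuals()` and `plot()` methods), and
`res$anova$richness` the type-2 ANOVA table. Passing `out_dir=` writes
every stage's tables (groups, abundances, diversity, partitioning,
resolution choices, coefficients, ANOVA) as CSV plus a JSON run manifest.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/run_pipeline.R --seed 1 --n-compartments 1000 --out out/
```

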