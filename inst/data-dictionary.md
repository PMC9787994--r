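# Data dictionary

All tabular files are UTF-8 CSV with a header row and '.' decimal
separator. Areas are hectares, heights and resolutions metres, logs
natural. Grids use 0-based array indexing with the origin at the
upper-left corner. Written by `run_forest_bird_analysis(..., out_dir=)`;
the input tables are also accepted by the `read_*_csv()` validators.

## compartments.csv (input/output)
- `compartment_id` — unique management-unit identifier.
- `management` — detailed management type (e.g. "Corsican pine
  monoculture", "Felled"); see `simplify_categories()` for the vocabulary.
- `age_class` — detailed age band ("Restock (0-6 years)" ... "Mixed
  ages", "Not applicable").
- `age_years` — stand age in years (empty for mixed/open).
- `area_ha` — compartment area (ha), > 0.

## survey.csv (input)
- `compartment_id`, `species_id` — keys.
- `visit` — 1 or 2; at most one record per (compartment, species, visit).
- `count` — non-negative integer count; absent rows mean zero.

## traits.csv (input)
- `species_id`; `body_mass_g` (continuous); `migratory`, `nest_site`,
  `diet`, `foraging_strata` (categorical).

## detectability.csv (input)
- `species_id`; `detectability` — species constant in (0, 1].

## structural_metrics.csv
- `compartment_id`; `tch_r<res>`, `gf_r<res>`, `hh_r<res>` for each
  resolution label in {0.5, 2, 5, 10} — top canopy height (m), gap
  fraction [0,1], Moran's I; `ve` — vertical evenness [0,1]; `sd_shrub` —
  shrub-layer PAD sum (relative units); `cd` — canopy-density PAD sum.

## groups.csv
- `group_id`; `management`, `age_class` (detailed pair defining the
  group); `management_simple`, `age_simple` (analysis levels);
  `n_members`; `total_area_ha`; `log_total_area` (natural log).

## group_abundance.csv
- `group_id` plus one column per species: detectability-corrected mean
  maximum count.

## diversity.csv
- `group_id`; `richness`; `shannon` (nats); `fric` (trait-space hull
  volume); `feve`, `fdiv` in [0,1]; `fdis` (trait-space distance).
  Empty cells mark undefined metrics (degenerate communities).

## transforms.csv
- `metric`; `lambda` (Box-Cox exponent, empty if untransformed); `shift`
  (constant added before transforming); `shapiro_p`.

## hp_results.csv
- `metric`; `variable`; `independent`, `joint` (R-squared units);
  `percent_independent`.

## resolution_choices.csv
- `metric`; `variable` (multi-resolution stem: tch, gf, hh);
  `resolution` (chosen label).

## selected_variables.csv
- `metric`; `variable` — the final model's predictor set.

## model_coefficients.csv
- `metric`; `term`; `estimate`; `std_error`; `p_value` (against the
  "Mixed" age-class and "Conifer" management baselines).

## anova.csv
- `metric`; `term`; `sum_sq`; `df`; `f_value`; `p_value` (type-2).

## manifest.json
- Seed, thresholds, resolutions and per-stage row counts of the run.

## Synthetic truth (in-memory only)
`generate_landscape()$truth`: `compartment_id`, `age_simple`,
`height_true`, `shrub_true`, `gap_true`, with attribute `dominant_driver`
= "age_class"; `simulate_bird_counts()$expected` holds expected counts.
Emitted alongside the data for validation and never read by the pipeline.
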