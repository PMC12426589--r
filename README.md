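# bruvkit

Analysis toolkit for spatially balanced baited remote underwater video
(BRUV) surveys of demersal fish, elasmobranch and macroinvertebrate
assemblages — the kind of fisheries-independent survey used to benchmark
marine protected areas in temperate waters.

It covers the full chain:

1. **Survey design** — generalized random tessellation stratified (GRTS)
   sampling on a discretised habitat frame, with exact per-stratum counts,
   a minimum-spacing rule (default 200 m) and a Voronoi balance
   diagnostic (`grts_sample`, `balance_metric`).
2. **Annotation ingest** — validation of frame-level annotation tables
   (EventMeasure-export-like CSV), MaxN computation
   (max over frames of the summed per-frame count, the standard
   double-counting-proof abundance metric), and demersal subsetting by a
   trait table (`read_annotations`, `compute_maxn`, `filter_demersal`).
3. **Ecological indices** — richness, summed-MaxN relative abundance,
   Shannon H′ (nats), variance/mean dispersion index, and biomass
   W = a·L^b per taxon with a four-tier proxy-length cascade
   (measured-in-sample → sub-habitat mean → study mean → registry
   reference; family-level taxa use the study family mean), plus
   Mann–Whitney / Kruskal–Wallis / Dunn habitat contrasts
   (`index_table`, `resolve_length`, `habitat_summary`).
4. **Covariates** — Horn 3×3 slope/aspect with circular-mean
   aggregation in a 200-m buffer, ruggedness, exposure
   (degrees from due west, 0–180), remoteness (distance to inhabited
   islands) and a Pearson + VIF collinearity screen
   (`terrain_stats`, `exposure`, `remoteness`, `collinearity_screen`).
5. **Spatial statistics** — 1-km² flat-top hexagon aggregation, 4-NN
   equal-weight spatially lagged response, and permutation Moran's I
   (`hex_aggregate`, `knn_lag`, `morans_i`).
6. **Model ranking** — Poisson / negative-binomial / gamma / Gaussian GLM
   candidate sets ranked by AICc with Akaike weights,
   deviance-explained pseudo-R² and the within-2-units confidence set
   (`build_candidate_set`, `fit_glm`, `aicc`, `rank_models`,
   `model_suite`).
7. **Rarefaction** — sample-based incidence interpolation, Chao2
   asymptote, extrapolation and seeded bootstrap bands
   (`incidence_counts`, `rarefy`, `chao2`, `extrapolate`,
   `bootstrap_ci`, `rarefaction_curve`).
8. **Synthetic seascape** — a seeded artificial archipelago (bathymetry,
   four sub-habitat strata, islands) and the full observation process
   (negative-binomial counts with habitat-specific depth effects,
   zero-inflated hyperabundant shoals, lognormal lengths with
   depth/remoteness/exposure effects, partial measurability) with
   recorded ground truth (`generate_seascape`, `species_pool`,
   `simulate_annotations`).

All artifacts are plain text: CSV tables, ESRI ASCII-grid rasters,
GeoJSON vector layers, JSON run reports.

## Worked example

Run the whole pipeline on the default synthetic world (280 deployments,
30 species, 10 × 10 km seascape) and look at the headline results:

```r
library(bruvkit)
cfg <- default_config(seed = 42, out_dir = "bruvkit_run")
report <- run_pipeline(cfg)
report
#> <bruv_report> seed 42, 7.5 s, stages: seascape > design > simulate >
#>   ingest > indices > covariates > spatial > models > rarefaction

idx <- report$objects$indices
round(c(mean_richness = mean(idx$richness),
        mean_abundance = mean(idx$abundance),
        DI_richness = dispersion_index(idx$richness),
        DI_abundance = dispersion_index(idx$abundance)), 2)
#>  mean_richness mean_abundance    DI_richness   DI_abundance
#>           8.10          31.25           0.61          77.37
```

Mean demersal richness is ~8 species per 60-min deployment with a
variance-to-mean dispersion index below 1 (Poisson-like, so richness is
modelled as Poisson), while summed MaxN is heavily overdispersed
(DI ≈ 77, driven by rare hyperabundant sand-eel-like shoals), motivating
the negative-binomial abundance model.

```r
head(report$objects$models$richness$ranking[,
       c("model", "aicc", "weight", "pseudo_r2", "delta_aicc")], 3)
#>               model     aicc weight pseudo_r2 delta_aicc
#> 1  depth_m + relief 1257.160  0.586     0.151      0.000
#> 2           depth_m 1258.868  0.250     0.130      1.708
#> 3 depth_m x habitat 1259.711  0.164     0.149      2.551
```

The AICc ranking for richness puts `depth + relief` on top with the
depth-only model inside the 2-unit confidence set — deeper, more complex
seabed carries more species in this generated world, matching the
built-in generator slopes. All ranked models include the 4-NN spatially
lagged response, and residual spatial autocorrelation is checked with a
permutation Moran's I.

Every stage also lands on disk (`plan.csv`, `annotations.csv`,
`indices.csv`, `ranking_*.csv`, `rarefaction.csv`, `report.json`) in
`cfg$out_dir`, and a thin CLI wraps the same calls
(`inst/cli/bruvkit run --seed 42 --out bruvkit_run`).

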