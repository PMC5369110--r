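# cyclexposure

Spatial analysis of crowdsourced intersection-level cycling counts split by
trip purpose. Given per-intersection ("node") counts of all-purpose and
commuting cycling activities, an areal partition, and a 1 km background
particulate-matter grid, the package answers three questions city
epidemiologists and transport planners ask of such data:

1. **Where is non-commuting (recreational) cycling concentrated?**
   Spatially contiguous clusters of high and low per-area non-commuting
   rates are detected with the AMOEBA ecotope-growing algorithm driven by
   the Getis–Ord Gi\* statistic.
2. **Do commuting and non-commuting cyclists face different air-pollution
   exposure?** Activity-weighted instantaneous PM₁₀/PM₂.₅ exposure means,
   WHO-guideline high-exposure percentages, and a weighted Wilcoxon
   rank-sum comparison.
3. **Can non-commuting counts be estimated when trip purpose is missing?**
   Per-node non-commuting counts are predicted from the all-purpose count
   plus locational features (distances to greenspace, water, the city
   centre; bus stops within 100 m) with OLS, MLP, SVM and random-forest
   regressions under 10-fold cross-validation, scored by the Pearson
   correlation of pooled out-of-fold predictions.

Because the motivating datasets (commercial cycling-app aggregates, national
air-quality grids) are not redistributable, the package ships a seeded
synthetic-study generator that emulates their statistical structure —
exponential-tailed activity counts, a commuting share varying with distance
to the centre, planted high-recreation regions, a PM surface declining from
the centre, and a small fraction of invalid records — together with the
ground truth needed for recovery tests.

## The statistics

**Non-commuting rate.** With per-node non-commuting counts inferred as
`count_total − count_commute` (after removing invalid nodes), each area *i*
aggregates the nodes inside it and

```
rate_non_act(i) = num_non_act(i) / (num_non_act(i) + num_com_act(i))
```

**Gi\* of a region.** For a study region of *N* areas with attribute values
x, mean x̄ and population standard deviation S, a candidate region R of n
areas scores

```
G*(R) = ( Σ_{i∈R} x_i − n·x̄ ) / ( S · sqrt( (N·n − n²) / (N − 1) ) )
```

AMOEBA grows a region from every seed area (sorting outer neighbors by
value and adopting the Gi\*-optimal prefix until no prefix improves),
attaches a Monte-Carlo permutation p-value to each candidate, keeps those
with p < α (default 0.01, 999 permutations), and resolves overlaps by
descending |Gi\*|. Areas receive integer solution values: ≥ 1 in a
high-value cluster, ≤ −1 in a low-value cluster, 0 outside.

**Exposure by purpose.** Each activity inherits the annual-mean pollutant
concentration of the grid cell containing its node; per-purpose means are
activity-count-weighted means over nodes, and the high-exposure percentage
is the activity fraction in cells with annual PM₂.₅ strictly above the WHO
guideline (10 µg/m³). The purpose comparison is a Wilcoxon rank-sum test on
the activity-expanded samples, computed directly from the weights via
midranks with tie correction.

## Worked example

```r
library(cyclexposure)

study <- generate_study(sim_config(seed = 42))
#> <study_bundle>
#>   nodes: 5000 (100 corrupted)
#>   areas: 400  pm cells: 100
#>   planted areas: 36  seed: 42

nodes <- infer_noncommute(clean_nodes(study$nodes)$kept)
rates <- noncommuting_rate(aggregate_to_areas(nodes, study$node_area, study$areas$id))
clusters <- run_amoeba(rates[, c("area_id", "rate_non_act")],
                       build_adjacency(study$areas),
                       alpha = 0.01, n_perm = 999, seed = 42)
clusters
#> <amoeba_clusters>
#>   400 areas (0 with undefined rate excluded)
#>   ecotopes kept at alpha = 0.01: 1 high, 1 low (n_perm = 999)
```

The single significant high cluster is the planted high-recreation region
(the generator plants a 3 km × 3 km block whose commuting share is 0.2
against a 0.6 background); its member set coincides with the 36 planted
areas (Jaccard overlap 1.0), with |Gi\*| ≈ 17.5. `tidy(clusters)` gives the
per-area table, `autoplot(clusters, study$areas)` the cluster map.

```r
exposure_report(study, clusters)
#> <exposure_summary>
#>   PM10 mean (ug/m^3): non-commute 11.621 vs commute 11.625 (one-sided p = 0.94)
#>   PM2.5 mean (ug/m^3): non-commute 8.739 vs commute 8.737 (one-sided p = 0.987)
#>   high-exposure share (PM2.5 > 10): non-commute 6.2% vs commute 7.1%
```

Under this default study the commuting share is spatially uniform outside
the planted region, so exposure means barely differ. Regenerate with a
commuting share that rises toward the centre
(`sim_config(commute_share_centre = 0.8, commute_share_edge = 0.3, planted_regions = list())`)
and the pattern flips decisively: non-commuting means fall below commuting
means with one-sided p < 10⁻¹⁰⁰, and the commuting high-exposure share is
roughly 2.3 times the non-commuting one.

```r
feats <- build_features(nodes, study$env_layers)
est <- estimate_purpose(feats, nodes$count_noncommute, models = c("OLS", "RF"),
                        k = 10, seed = 42)
est
#> <purpose_cv> pooled out-of-fold Pearson correlations
#>  model pearson_r mean_fold_r  k seed
#>    OLS 0.8301353   0.8297503 10   42
#>     RF 0.8245537   0.8252402 10   42
```

`autoplot(est)` plots predicted vs observed counts per model. The whole
chain — simulate, clean, rates, clusters, exposure, estimation, with every
artifact persisted and a JSON run manifest — is available as
`run_pipeline(pipeline_config(...), out_dir)` or through the thin CLI
wrapper: `Rscript inst/exec/cyclexposure run-all --config cfg.yaml --out run/`.

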