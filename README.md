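# aggrepaint

Quantitative analysis of protein aggregates in DNA-PAINT single-molecule
localization data.

DNA-PAINT images a labeled protein as a point cloud: each transient binding
of a dye-coupled imager oligo yields one localization, and the number of
localizations in a structure scales linearly with the number of labeled
targets. `aggrepaint` turns such point clouds into quantitative aggregate
biology, as developed for phospho-tau aggregates in human brain tissue:

1. **Segmentation** — Voronoi tessellation of the localizations; cells with
   area ≤ a density threshold (default 3×10⁻⁴ µm²) are clustered along
   shared cell edges; clusters with < 10 localizations are discarded.
   Aggregate boundaries and areas come from alpha shapes (α = 0.05 µm).
2. **Filtering** — a robust log–log trend of localization count vs. area
   removes imaging artifacts (|residual| > 3 robust scales); a
   dye-specific background area threshold (0.004 µm² Cy3b-type /
   0.006 µm² ATTO655-type, or calibrated to remove ≥ 97% of
   negative-control objects) removes background puncta.
3. **Classification** — nano \[threshold, 0.017), intermediate
   \[0.017, 0.15) and micro \[0.15, ∞) µm² aggregates.
4. **Morphology** — a fixed registry of 67 descriptors per aggregate
   (point/density, geometric, moment, boundary, skeleton, fractal,
   composite families) computed from the raw point cloud; PCA after
   unit-variance scaling; group similarity as the Jaccard index
   (intersection over union) of group footprints in the PC1–PC2 plane.
5. **Dual color** — 200-frame laser-block demultiplexing; merged-reference
   segmentation; alpha-shape overlap score per cluster with re-segmentation
   of sub-0.15 µm² clusters scoring < 30%; per-aggregate enrichment score
   `(n_A − n_B)/(n_A + n_B)` with singly (|s| > 0.8) vs. dually (|s| ≤ 0.8)
   modification calls.
6. **Reporting** — aggregate densities per unit area, class and
   modification percentages, Wilcoxon rank-sum tests on per-replicate
   means (exact for small samples), and dual-labeling steric-hindrance
   controls.

A synthetic-data generator (`generate_fov()`, `generate_cohort()`) plants
aggregates of the three size classes with controlled two-channel
composition, jitter, background and sub-threshold noise clusters, labeling
every localization, so the whole pipeline is validated against ground
truth without raw imaging data.

## Worked example

```r
library(aggrepaint)

sim <- generate_fov(rng_seed = 11)          # 50 x 50 um field, 19 planted aggregates
res <- analyze_fov(sim$fov)                 # segment -> filter -> classify
tab <- aggregate_table(res$clusters)
table(tab$size_class)
#> intermediate        micro         nano
#>            5            2           12
density_per_unit_area(res$clusters, sim$fov)
#> [1] 0.0076
head(tab[, c("id", "n_locs", "area", "size_class")], 5)
#>   id n_locs    area size_class
#> 1  1    101 0.00491       nano
#> 2  2    129 0.00651       nano
#> 3  3    123 0.00601       nano
#> 4  4     97 0.00563       nano
#> 5  5    100 0.00559       nano

rec <- recovery_metrics(res$clusters, sim$truth)
mclust::adjustedRandIndex(rec$pairs$recovered, rec$pairs$planted)
#> [1] 0.9999
```

All 19 planted aggregates are recovered with their planted size classes;
the per-localization Adjusted Rand Index against the planted labels is
0.9999, and the measured nano areas (~0.005–0.007 µm²) sit inside the nano
class window, consistent with a ~90 nm average diameter.

## Analysis workflow

The `analysis/` scripts run the study end to end on simulated cohorts and
write tidy tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | four-group single-color cohort (control / PART-like / AD-like / dephosphorylated), localization CSVs + ground truth under `scratch/sim/` |
| `02_segment_classify.R` | per-FOV segmentation, filtering, classification; cohort density and class-percentage tables |
| `03_morphology_pca.R` | 67-descriptor profiles of nano-aggregates, PCA, pairwise group Jaccard overlaps, log10 morphology panels |
| `04_dual_color.R` | two-channel cohorts with different planted singly/dually mixes; overlap QC; modification percentages |
| `05_report.R` | rank-sum group comparisons, one-sided dephosphorylation test, steric-hindrance controls, run manifest |

Run them in order with `Rscript analysis/01_simulate.R` etc. On the default
seeds the AD-like group's nano-aggregates (planted with a distinct blob
morphology) separate from control/PART-like in the embedding
(pairwise Jaccard 0.04/0.09 vs. 0.51 between control and PART-like), and
the planted dually-modified fractions of 26.4% / 59.7% in the two
dual-color stages are recovered as 26.5% / 58.6%.

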