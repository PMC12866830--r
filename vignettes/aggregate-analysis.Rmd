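---
title: "Quantifying protein aggregates in DNA-PAINT point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein aggregates in DNA-PAINT point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrepaint)
```

## The problem

DNA-PAINT super-resolution microscopy images a labeled protein as a cloud of
localizations: each transient binding event of a dye-coupled imager oligo to
an antibody-coupled docking strand yields one fitted emitter position. A
protein aggregate therefore appears not as a contiguous image object but as
a locally dense set of points in an otherwise sparse field, and the number
of localizations inside an aggregate scales linearly with the number of
labeled target proteins it contains. `aggrepaint` implements the full
quantitative chain for such data as applied to phospho-tau aggregates in
human brain tissue: density-based segmentation, artifact and background
filtering, size classification, morphological profiling, and two-channel
composition scoring — together with a synthetic-data generator that plants
known aggregates so that every stage can be validated against ground truth.

## Segmentation model

Each localization receives a Voronoi cell; the cell area is an inverse
density estimate. Localizations whose bounded cell area is at most
`voronoi_area_threshold` are "dense"; connected components of dense
localizations under Voronoi-cell adjacency (shared cell edges, equivalently
Delaunay edges) form candidate aggregates; components with fewer than
`min_locs = 10` localizations are discarded (the bound is inclusive: a
10-localization cluster survives).

Three choices deserve comment:

* **Cell areas from the Delaunay dual.** Cell areas are computed by the
  exact signed decomposition of each Delaunay triangle into
  vertex–edge-midpoint–circumcenter quadrilaterals. Because both
  circumcenters adjacent to an edge lie on that edge's perpendicular
  bisector together with the edge midpoint, the signed quad areas telescope
  to the exact dual-cell (Voronoi) area, including obtuse triangles whose
  circumcenter falls outside. Cells of convex-hull points are unbounded and
  are treated as failing the density threshold — they sit at the field
  border where the area is undefined.
* **Thresholds are density-matched, not universal.** In tissue data the
  threshold is tuned per case to the aggregate burden and localization
  density (from 1.8e-4–3e-4 um^2 in low-burden tissue up to beyond 2e-3
  um^2 in heavily burdened tissue). The package default, 3e-4 um^2, is the
  top of the low-burden range and matches the synthetic generator's default
  localization density (see below). Ties at the threshold are retained
  (inclusive comparison), mirroring the inclusive minimum-localization
  bound.
* **Aggregate area is the alpha-shape area of its members** (not the sum of
  Voronoi cell areas): the dual-color stage explicitly represents
  aggregates as alpha shapes, and using one area definition throughout
  keeps the size-class windows consistent. The alpha complex keeps Delaunay
  triangles with circumradius at most `alpha_radius` (default 0.05 um,
  roughly four times the typical localization spacing inside an aggregate);
  degenerate complexes fall back to the convex hull. The boundary is traced
  from directed triangle edges, so outer contours come out
  counter-clockwise and holes clockwise, and polygon-clipping operations
  (intersection, union) are exact on them.

## Filtering and classification

Filters run in a fixed order: artifact removal, background removal, then
classification.

**Artifacts.** Genuine aggregates show a tight positive trend between
alpha-shape area and localization count; fluorescent junk deviates wildly
(tiny area with enormous counts, or the reverse). The filter fits a
least-absolute-deviations line to log10(count) versus log10(area) and
removes clusters whose residual exceeds `cutoff_k = 3` times a per-cluster
scale: the larger of the cohort MAD and the cluster's own Poisson counting
noise `1/(ln 10 * sqrt(n))` on the log10 scale. The counting-noise floor
matters when the cohort trend is very tight (few-percent residuals): a
50-localization cluster legitimately fluctuates by ~15% in count, and
flagging it as an artifact would systematically delete small real
aggregates. A genuine artifact, tens of times off the trend, exceeds both
scales. Below 10 clusters the trend is not estimable and the filter is
skipped with a warning.

**Background.** Negative controls (no primary antibody) still produce small
segmented puncta. An area threshold calibrated on such controls removes
them: fixed dye-specific defaults of 0.004 um^2 (Cy3b-type imagers) and
0.006 um^2 (ATTO655-type, slightly noisier), or a percentile mode that
returns the smallest observed area removing at least 97% of
negative-control objects. The keep rule is inclusive (`area >= threshold`).
The percentile implementation takes the next order statistic above the
target quantile rather than an interpolated quantile, so the guaranteed
removal fraction holds exactly at small sample sizes.

**Size classes.** Surviving aggregates are classified by area:
nano `[background threshold, 0.017)`, intermediate `[0.017, 0.15)`, micro
`[0.15, Inf)` um^2. The printed boundaries appear in two ranges each, so a
convention is required; windows here are half-open on the right, giving the
shared endpoint to the larger class. The nano lower bound is the
dye-specific background threshold.

## Morphological descriptors

`compute_descriptors()` returns a fixed registry of 67 features per
aggregate, computed from the raw point cloud without rendering, in seven
families: point/density statistics (8), geometric (16), moment-based (12),
boundary (12), skeleton (10), fractal/heterogeneity (4) and composite (5).
The exact descriptor set used in the original ECLiPSE-style tissue analyses
is published separately, so
the registry here is this package's own fixed, documented set with the same
dimensionality and family structure; what matters downstream is a
consistent, translation-invariant, scale-covariant profile.

Numerical conventions:

* Boundary descriptors use the longest alpha-shape contour resampled to 128
  arc-length-uniform points; curvature comes from central differences on
  the closed resampled curve. The resampling density is a fixed choice —
  curvature statistics are only comparable within a fixed convention.
* Skeleton descriptors rasterize the alpha shape on a grid anchored to the
  shape's bounding box (64 pixels along the longer side), thin it with the
  Zhang–Suen algorithm, and analyze the skeleton pixel graph (diagonal
  edges that shortcut an existing orthogonal connection are pruned).
  Anchoring the grid to the bounding box makes these descriptors exactly
  translation invariant and scale-proportional.
* Hu moments are normalized by the alpha-shape area as the size measure
  (`eta_pq = mu_pq / (n * A^((p+q)/2))`): the classical pixel-count
  normalization has no analogue for a point sample whose size does not
  grow under dilation, and this form is dimensionless and
  dilation-invariant.
* Fractal descriptors (box-counting of boundary and cloud, correlation
  dimension, gliding-box lacunarity) use scales relative to the bounding
  box, again for translation/scale behaviour; the correlation dimension
  subsamples deterministically (every k-th point) above 600 points.
* The two composite Voronoi descriptors (within-cluster cell-area mean and
  CV) come from a tessellation of the member points alone in a padded
  bounding box, with window-clipped cells excluded.

Descriptors are undefined for degenerate geometry (collinear point sets)
and for clusters below 10 localizations; both raise errors naming the
offending family rather than returning silent NAs.

## PCA and group overlap

Descriptor matrices are embedded by PCA after centering and unit-variance
scaling (zero-variance features are dropped with a message — `skel_cycles`
is frequently constant on compact aggregates). Component signs are fixed by
making each loading's largest-magnitude entry positive, so embeddings are
reproducible. Group similarity is scored as the Jaccard index
(intersection over union) of footprint polygons built from each group's
scores in the PC1–PC2 plane: alpha-shape footprints with a data-adaptive
radius (three times the median nearest-neighbour distance) after trimming
the most extreme 1% of points per group, with a convex-hull option. The
tissue analyses describe the overlap as intersection divided by the sum of
the sets while naming the Jaccard index; intersection-over-union is the default here and
the literal sum-denominator variant is available via `method = "sum"`.
Overlap is computed in the PC1–PC2 plane by default (the first three
components are usually plotted for visualization, but a polygon overlap is a
planar construct); `pairwise_group_overlap()` can report any plane.

## Dual-color pipeline

Two-channel acquisitions interleave excitation lasers in 200-frame blocks
(68000 frames total), so localizations are demultiplexed by integer
division of the frame index. The two channels are pooled into a merged
reference, segmented and filtered exactly as a single-color image, and each
cluster keeps per-channel member counts.

A quality-control step catches spurious merges of two adjacent
single-channel aggregates: each channel's members are turned into an alpha
shape and the directional overlaps (percent of one shape's area
intersecting the other) are computed. The score is the minimum of the two
directions — the two directional values are expected to agree for genuine
dual-labeled aggregates, and a single decision value is needed for the
gate; the minimum is the conservative choice. Clusters above 0.15 um^2
pass untouched (the area gate applies first; micro-sized aggregates
consistently overlap), while smaller clusters scoring below 30% are
re-segmented per channel with identical parameters. Re-segmentation can
orphan a few boundary localizations (they may fail the density threshold in
the thinner single-channel cloud); orphans are attached to the nearest
resulting sub-cluster so the output still partitions the original members
and no localization is lost. Fragments that fall below the background
threshold after splitting are dropped from the classified output.

Composition is scored per aggregate as `(n_A - n_B) / (n_A + n_B)`, in
[-1, 1]: +/-1 means a single phospho-mark, 0 an equal mix. Scores with
absolute value above 0.8 are "singly modified", everything in [-0.8, 0.8]
(boundary inclusive, reading the published "between") is "dually
modified". The merged-reference background threshold defaults to the
0.004 um^2 (Cy3b) value; with the synthetic noise model producing
sub-0.002 um^2 noise footprints this separates noise from aggregates
without sacrificing small genuine nano-aggregates, and it is configurable
where a different dye combination warrants 0.006 um^2.

## Statistics

Group comparisons use the unpaired Wilcoxon rank-sum test on per-replicate
means — never on per-FOV values, which are pseudo-replicates of the same
tissue section. Exact small-sample p-values are used where there are no
ties, the normal approximation with tie and continuity correction
otherwise; a one-sided variant serves directional hypotheses such as "the
dephosphorylation treatment decreases nano-aggregate density". No
multiple-testing correction is applied, matching the unadjusted reporting
convention of the source analyses. Two controls address steric hindrance in
dual labeling: the correlation of per-channel localization counts across
aggregates (hindrance would push it negative; shared aggregate size pushes
it positive) and a rank-sum comparison of per-aggregate localization counts
between matched single- and dual-color runs.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with every localization labeled by its source:

* **Planted aggregates** in three classes with class-mean characteristic
  sizes of 0.09 um (nano, discs), 0.5 um (intermediate, aspect-2 ellipses)
  and 1.6 um (micro, fibril-like chains: smoothed random polylines with
  uniform transverse spread), sizes drawn lognormally with an 8%
  coefficient of variation. Only class-average sizes are reported for the
  tissue aggregates; the spread is this package's choice, set so that measured
  alpha-shape areas fall within the published class windows with high
  probability.
* **Localization counts proportional to area** at a default density of
  20000 localizations per um^2 of planted support. The density and the
  default Voronoi threshold are matched deliberately: the threshold trims
  an aggregate's outermost localization ring (edge cells open into empty
  background), and at lower densities that shrinkage pushes measured nano
  areas below the 0.004 um^2 background threshold. At the default pairing,
  measured nano areas center near 0.006 um^2 — consistent with a ~90 nm
  average diameter being itself a measured quantity.
* **Localization jitter** of 0.01 um (a typical DNA-PAINT localization
  precision), folded together with
  repeat detections into the per-aggregate count — downstream analysis
  never uses frame dynamics, so blinking kinetics are not modeled.
* **Channel composition**: each aggregate's channel-A fraction is drawn
  from a mixture (pure A, pure B, or a Beta-distributed dually modified
  component) and realized as an exact count `round(p * n)` at random
  positions. The exact-count convention makes the realized composition
  match the planted enrichment to within 1/n, so recovery error measures
  the pipeline, not binomial sampling noise. Frames are stamped consistent
  with the 200-frame laser blocks, so demultiplexing is testable
  end-to-end.
* **Noise**: a uniform background (default 5 localizations per um^2) plus
  sparse noise clusters (3–8 localizations in ~50 nm discs), both below
  the minimum-localization and background-area filters by construction —
  emulating the published negative-control behaviour in which >97% of
  segmented control objects are removed.
* **Hierarchy**: cohorts are generated as group -> replicate -> FOV with
  per-FOV seeds derived deterministically from one master seed.

What the generator does **not** emulate: binding kinetics and photon
statistics, camera noise, chromatic offsets between channels, drift, 3D
structure, and spatially varying background (autofluorescence). Passing the
recovery tests therefore demonstrates the correctness of the segmentation,
filtering, classification and scoring logic under the stated statistical
model — not robustness to every optical artifact of real tissue data, and
the published patient-derived numbers (densities per Braak stage, tissue
PCA overlaps, dually-modified transitions) are emulated qualitatively, not
reproduced.

## Problem sizes and validation scale

The packaged validation suite works at desk scale, chosen to exercise every
code path at statistically meaningful sizes: recovery checks use eight
50 x 50 um fields of view with 19 planted aggregates each (~40000
localizations per field), segmentation is cross-checked against an
exhaustive component-search oracle on 50 random instances of up to 500
points, Voronoi geometry against a nearest-site grid oracle and a
brute-force circumcircle Delaunay oracle, and rank-sum p-values against
exhaustive permutation enumeration for group sizes up to 8. The analysis
scripts under `analysis/` run a smaller 30 x 30 um cohort (24 fields across
four burden groups, ~420000 localizations) end to end.

## Known limitations

* Segmentation quality degrades gracefully but monotonically as the
  Voronoi threshold approaches the inverse localization density of the
  structures of interest; the threshold remains a per-dataset choice, as
  in the tissue analyses this pipeline mirrors (thresholds are confirmed
  visually there), not an auto-tuned quantity.
* Alpha shapes with a fixed radius under-resolve structures whose local
  point spacing approaches the radius; for very sparse clusters the hull
  fallback overestimates area.
* The skeleton and lacunarity descriptors depend on raster resolution
  (fixed at 64 pixels on the longer side); they are comparable across
  aggregates, not absolute measurements.
* The re-segmentation step assumes exactly two channels and perfect
  channel registration; chromatic-offset correction is out of scope.
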